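# Internal helpers: error signalling, apportionment, hashing.

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bv_parameter_error", "bv_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bv_input_error", "bv_error")))
}

stop_calibration <- function(msg, ..., data = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c("bv_calibration_error", "bv_error"))
  cond$data <- data
  stop(cond)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Largest-remainder apportionment of an integer total over non-negative
# weights. Deterministic: ties on the fractional part go to the earlier index.
apportion <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  n <- length(weights)
  if (total == 0 || n == 0L || sum(weights) == 0) return(integer(n))
  q <- total * weights / sum(weights)
  f <- floor(q + 1e-9)                      # guard exact-integer float dust
  r <- as.integer(round(total - sum(f)))
  if (r > 0L) {
    o <- order(q - f, decreasing = TRUE)
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}

# Round half away from zero (documented convention for reported integers).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over the UTF-8 bytes of a string; returned as 8 hex digits.
# Used as a content hash for calibration provenance in reports.
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(x, collapse = ""))))
  two32 <- 2^32
  # bitwXor works on 32-bit signed ints; keep the arithmetic in doubles split
  # into 16-bit halves so every intermediate stays exactly representable.
  h <- 2166136261
  for (b in bytes) {
    hx <- h %% two32
    xb <- bitwXor(as.integer(hx %% 2^16), b) + floor(hx / 2^16) * 2^16
    lo <- xb %% 2^16
    hi <- floor(xb / 2^16)
    h <- (lo * 16777619 + ((hi * 16777619) %% 2^16) * 2^16) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

# Pixel matrix of a channel_image (matrix rows = image rows / y).
px_of <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_input("expected a channel_image or numeric matrix")
}
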