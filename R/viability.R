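#' Thresholded sum intensity of one channel
#'
#' The assay's core statistic: the sum of grey levels (0-255) over all
#' pixels selected by a low/high threshold window. With the low threshold
#' calibrated to exclude background, the sum intensity of a channel is
#' proportional to the number of cells stained in that channel, which is
#' what makes the viability formula quantitative.
#'
#' @param image A [channel_image()] or a numeric pixel matrix.
#' @param low Integer low threshold in `[0, high]`; a pixel is selected when
#'   `low <= pixel <= high` (both bounds inclusive).
#' @param high High threshold, fixed at the 8-bit maximum 255 by default.
#' @return An object of class `sum_intensity`: list with `channel`, `value`
#'   (the sum) and `n_selected` (selected pixel count).
#' @examples
#' img <- matrix(c(40, 41, 255, 0), 2, 2)
#' sum_intensity(img, low = 41)$value  # 296: 41 and 255 are selected
#' @export
sum_intensity <- function(image, low, high = 255) {
  if (!is_scalar_number(low) || !is_scalar_number(high) ||
      low < 0 || high > 255 || low > high)
    stop_param("thresholds must satisfy 0 <= low <= high <= 255")
  px <- px_of(image)
  sel <- px >= low & px <= high
  structure(list(channel = if (inherits(image, "channel_image")) image$channel
                 else NA_character_,
                 value = sum(px[sel]),
                 n_selected = sum(sel),
                 low = low, high = high),
            class = "sum_intensity")
}

#' @export
print.sum_intensity <- function(x, ...) {
  cat(sprintf("<sum_intensity> %s: %.6g over %d px (window [%g, %g])\n",
              if (is.na(x$channel)) "?" else toupper(x$channel),
              x$value, x$n_selected, x$low, x$high))
  invisible(x)
}

#' Viability percentage from paired sum intensities
#'
#' `100 * S_FDA / (S_FDA + S_PI)`, valid when both channels were acquired
#' under a matched calibration (equal live and dead cell numbers give equal
#' sum intensity). When both signals are zero the viability is undefined and
#' `NA` is returned with attribute `undefined = TRUE` rather than an
#' arbitrary 0 or 100.
#'
#' @param s_fda,s_pi [sum_intensity()] objects or bare non-negative numbers.
#' @return Viability percent in `[0, 100]`, or flagged `NA`.
#' @export
compute_viability <- function(s_fda, s_pi) {
  f <- if (inherits(s_fda, "sum_intensity")) s_fda$value else s_fda
  p <- if (inherits(s_pi, "sum_intensity")) s_pi$value else s_pi
  if (!is_scalar_number(f) || !is_scalar_number(p) || f < 0 || p < 0)
    stop_param("sum intensities must be non-negative numbers")
  if (f + p == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * f / (f + p)
}

#' Quantify viability over one or more bead fields
#'
#' Applies the calibrated sum-intensity method to a set of registered
#' FDA/PI fields. The primary (pooled) estimate applies the viability
#' formula to sum intensities summed across all fields, weighting each
#' field by its signal; per-field percentages are reported alongside. With
#' `per_bead = TRUE`, beads are segmented ([segment_beads()]) and the
#' formula is applied per bead region.
#'
#' The validated protocol images at least five fields and ~100 beads per
#' condition; a warning (never a silent change of result) is issued below
#' those minima.
#'
#' @param fields A [bead_field()] or list of them (equal image dimensions).
#' @param config A [calibration_config()].
#' @param per_bead Also compute per-bead viability via segmentation.
#' @param seg_args List of extra arguments passed to [segment_beads()].
#' @return An object of class `viability_result` with elements `percent`
#'   (pooled), `undefined` flag, `s_fda`/`s_pi` (pooled sums), `per_field`
#'   data frame, optional `per_bead` data frame, counts and the triggered
#'   warnings.
#' @export
quantify <- function(fields, config = default_calibration(),
                     per_bead = FALSE, seg_args = list()) {
  if (inherits(fields, "bead_field")) fields <- list(fields)
  if (!length(fields) || !all(vapply(fields, inherits, TRUE, "bead_field")))
    stop_param("fields must be bead_field objects")
  if (!inherits(config, "calibration_config"))
    stop_param("config must be a calibration_config")
  dims <- vapply(fields, function(f) dim(f$fda$pixels), integer(2))
  if (length(fields) > 1 && any(dims != dims[, 1]))
    stop_input("all fields must share the same image dimensions")

  warnings_out <- character()
  note <- function(rule, msg) {
    warnings_out[[rule]] <<- msg
    warning(msg, call. = FALSE)
  }
  if (length(fields) < 5)
    note("min_fields", sprintf(
      "only %d field(s) supplied; the validated protocol images at least 5 fields per condition",
      length(fields)))

  sf <- sp <- 0
  per_field <- data.frame(field = seq_along(fields), percent = NA_real_,
                          s_fda = NA_real_, s_pi = NA_real_)
  for (i in seq_along(fields)) {
    a <- sum_intensity(fields[[i]]$fda, config$low_fda, config$high)
    b <- sum_intensity(fields[[i]]$pi, config$low_pi, config$high)
    per_field$s_fda[i] <- a$value
    per_field$s_pi[i] <- b$value
    per_field$percent[i] <- suppressWarnings(compute_viability(a$value, b$value))
    sf <- sf + a$value
    sp <- sp + b$value
  }

  per_bead_df <- NULL
  n_beads <- NA_integer_
  truth_beads <- vapply(fields, function(f)
    if (is.null(f$truth)) NA_integer_ else nrow(f$truth$beads), integer(1))
  if (!anyNA(truth_beads)) n_beads <- sum(truth_beads)
  if (per_bead) {
    rows <- list()
    detected <- 0L
    for (i in seq_along(fields)) {
      seg <- do.call(segment_beads, c(list(fields[[i]], config = config),
                                      seg_args))
      detected <- detected + nrow(seg$beads)
      if (!nrow(seg$beads)) next
      fpx <- fields[[i]]$fda$pixels
      ppx <- fields[[i]]$pi$pixels
      lab <- seg$labels
      for (j in seq_len(nrow(seg$beads))) {
        m <- lab == seg$beads$bead[j]
        av <- fpx[m]; bv <- ppx[m]
        s1 <- sum(av[av >= config$low_fda & av <= config$high])
        s2 <- sum(bv[bv >= config$low_pi & bv <= config$high])
        rows[[length(rows) + 1L]] <- data.frame(
          field = i, bead = seg$beads$bead[j],
          x_px = seg$beads$x_px[j], y_px = seg$beads$y_px[j],
          radius_px = seg$beads$radius_px[j],
          s_fda = s1, s_pi = s2,
          percent = suppressWarnings(compute_viability(s1, s2)))
      }
    }
    per_bead_df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(field = integer(), bead = integer(), x_px = numeric(),
                 y_px = numeric(), radius_px = numeric(), s_fda = numeric(),
                 s_pi = numeric(), percent = numeric())
    if (is.na(n_beads)) n_beads <- detected
  }
  if (!is.na(n_beads) && n_beads < 100)
    note("min_beads", sprintf(
      "only %d bead(s) in the analysed fields; the validated protocol uses ~100 beads per condition",
      n_beads))

  pooled <- compute_viability(sf, sp)
  structure(list(
    percent = as.numeric(pooled),
    undefined = isTRUE(attr(pooled, "undefined")),
    s_fda = sf, s_pi = sp,
    per_field = per_field,
    per_bead = per_bead_df,
    n_fields = length(fields),
    n_beads = n_beads,
    config = config,
    warnings = warnings_out
  ), class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat("<viability_result>\n")
  if (x$undefined) {
    cat("  viability: undefined (no signal in either channel)\n")
  } else {
    cat(sprintf("  pooled viability: %.2f %%\n", x$percent))
  }
  cat(sprintf("  fields: %d | beads: %s | S_FDA %.5g | S_PI %.5g\n",
              x$n_fields, ifelse(is.na(x$n_beads), "?", x$n_beads),
              x$s_fda, x$s_pi))
  if (!is.null(x$per_bead))
    cat(sprintf("  per-bead table: %d rows\n", nrow(x$per_bead)))
  if (length(x$warnings))
    cat(sprintf("  warnings: %s\n", paste(names(x$warnings), collapse = ", ")))
  invisible(x)
}

#' @export
summary.viability_result <- function(object, ...) {
  print(object)
  pf <- object$per_field$percent
  if (length(pf) > 1)
    cat(sprintf("  per-field: mean %.2f, sd %.2f, range [%.2f, %.2f]\n",
                mean(pf, na.rm = TRUE), stats::sd(pf, na.rm = TRUE),
                min(pf, na.rm = TRUE), max(pf, na.rm = TRUE)))
  if (!is.null(object$per_bead) && nrow(object$per_bead))
    cat(sprintf("  per-bead: median %.2f, IQR [%.2f, %.2f]\n",
                stats::median(object$per_bead$percent, na.rm = TRUE),
                stats::quantile(object$per_bead$percent, 0.25, na.rm = TRUE),
                stats::quantile(object$per_bead$percent, 0.75, na.rm = TRUE)))
  invisible(object)
}
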