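# Calibration: exposure selection by SNR, low-threshold fitting, and
# matching the PI set-up to the FDA set-up so that equal numbers of live and
# dead cells produce the same sum intensity (the equivalence the viability
# formula requires).

# Logical cell-pixel mask for one channel of a field. Synthetic fields use
# ground truth (the discs of beads that carry cells stained in this
# channel); real fields fall back to a provisional Otsu split.
cell_mask <- function(field, channel) {
  px <- field[[channel]]$pixels
  if (!is.null(field$truth)) {
    b <- field$truth$beads
    n_ch <- if (channel == "fda") b$n_live else b$n_dead
    b <- b[n_ch > 0, , drop = FALSE]
    mask <- matrix(FALSE, nrow(px), ncol(px))
    if (!nrow(b)) return(mask)
    xs <- matrix(rep(seq_len(ncol(px)), each = nrow(px)), nrow(px))
    ys <- matrix(rep(seq_len(nrow(px)), ncol(px)), nrow(px))
    for (i in seq_len(nrow(b))) {
      r_px <- b$diameter_um[i] / 2 / field[[channel]]$pixel_size_um
      mask <- mask | ((xs - b$center_x_px[i])^2 +
                        (ys - b$center_y_px[i])^2 <= r_px^2)
    }
    mask
  } else {
    thr <- EBImage::otsu(EBImage::Image(px / 255)) * 255
    px > thr
  }
}

# Per-channel cell regions (list of pixel-index vectors), used by threshold
# fitting to check that a candidate level retains every region.
cell_regions <- function(field, channel) {
  px <- field[[channel]]$pixels
  if (!is.null(field$truth)) {
    b <- field$truth$beads
    n_ch <- if (channel == "fda") b$n_live else b$n_dead
    b <- b[n_ch > 0, , drop = FALSE]
    if (!nrow(b)) return(list())
    xs <- matrix(rep(seq_len(ncol(px)), each = nrow(px)), nrow(px))
    ys <- matrix(rep(seq_len(nrow(px)), ncol(px)), nrow(px))
    lapply(seq_len(nrow(b)), function(i) {
      r_px <- b$diameter_um[i] / 2 / field[[channel]]$pixel_size_um
      which((xs - b$center_x_px[i])^2 + (ys - b$center_y_px[i])^2 <= r_px^2)
    })
  } else {
    thr <- EBImage::otsu(EBImage::Image(px / 255)) * 255
    lab <- EBImage::bwlabel(px > thr)
    lab <- EBImage::imageData(lab)
    ids <- setdiff(unique(as.integer(lab)), 0L)
    regs <- lapply(ids, function(id) which(lab == id))
    regs[vapply(regs, length, 1L) >= 5L]
  }
}

# Robust background level of a pixel grid: histogram mode plus k MADs
# (MAD centred on the mode, normal-consistent).
background_ceiling <- function(px, k = 3) {
  v <- as.integer(round(px))
  mode_v <- which.max(tabulate(v + 1L, nbins = 256L)) - 1L
  mode_v + k * stats::mad(v, center = mode_v)
}

#' Select the exposure time maximising signal-to-noise ratio
#'
#' SNR is defined as the sum intensity of pixels representing cells divided
#' by the sum intensity of pixels without cells. Candidates whose saturated
#' pixel fraction exceeds `max_saturated_fraction` are excluded (a clipped
#' image can no longer report sum intensity linearly); among the rest the
#' highest-SNR candidate wins, with ties broken toward the shorter exposure
#' (less photodamage, less clipping risk). In the noiseless unclipped limit
#' both numerator and denominator scale linearly with exposure, so all
#' candidates tie and the shortest is returned.
#'
#' @param fields List of [bead_field()]s of the same scene acquired at the
#'   candidate exposures (at least one field per candidate; a field's
#'   exposure is read from its channel metadata).
#' @param channel `"fda"` or `"pi"`.
#' @param candidates Candidate exposure times in milliseconds. The
#'   validated instrument offered 100/150/200/300/400 ms for FDA and
#'   600/800/1000/2000 ms for PI.
#' @param max_saturated_fraction Largest tolerated fraction of pixels at
#'   255.
#' @param snr_tol Relative tolerance within which two SNRs count as tied.
#' @return List of class `exposure_selection`: `exposure_ms` (the choice)
#'   and `reports`, a data frame of per-candidate SNR and saturation.
#' @export
select_exposure <- function(fields, channel = c("fda", "pi"), candidates,
                            max_saturated_fraction = 0.01, snr_tol = 1e-6) {
  channel <- match.arg(channel)
  if (!length(candidates)) stop_param("candidates must be a non-empty list of exposures")
  if (inherits(fields, "bead_field")) fields <- list(fields)
  expos <- vapply(fields, function(f) f[[channel]]$exposure_ms, 1)
  snr <- sat <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    idx <- which(expos == candidates[j])
    if (!length(idx))
      stop_param("no field acquired at candidate exposure %g ms", candidates[j])
    s <- t <- numeric(length(idx))
    for (ii in seq_along(idx)) {
      f <- fields[[idx[ii]]]
      px <- f[[channel]]$pixels
      m <- cell_mask(f, channel)
      denom <- sum(px[!m])
      s[ii] <- if (denom > 0) sum(px[m]) / denom else Inf
      t[ii] <- mean(px >= 255)
    }
    snr[j] <- mean(s)
    sat[j] <- mean(t)
  }
  ok <- sat <= max_saturated_fraction
  if (!any(ok))
    stop_calibration("all candidate exposures exceed the saturation limit (%g)",
                     max_saturated_fraction)
  best <- max(snr[ok])
  tied <- ok & snr >= best * (1 - snr_tol)
  choice <- min(candidates[tied])
  structure(list(exposure_ms = choice,
                 reports = data.frame(exposure_ms = candidates, snr = snr,
                                      saturated_fraction = sat,
                                      excluded = !ok)),
            class = "exposure_selection")
}

#' @export
print.exposure_selection <- function(x, ...) {
  cat(sprintf("<exposure_selection> chosen exposure: %g ms\n", x$exposure_ms))
  print(x$reports)
  invisible(x)
}

#' Fit the low threshold of a channel from calibration fields
#'
#' Per field, the low threshold is the smallest integer grey level that
#' separates background from cells: strictly above the robust background
#' ceiling (histogram mode + `k` MADs) while still capturing every cell
#' region. The returned value is the mean of the per-field thresholds,
#' rounded half-up (per-field thresholds are integers; the rounding
#' convention is documented rather than assumed).
#'
#' The validated protocol averages 10 images of 40-60 beads each, including
#' two high-density samples (22 and 26 million cells/mL of beads); a
#' warning is issued when fewer fields are supplied. Fields with no
#' detectable cells (e.g. background-only controls) are excluded with a
#' warning, never averaged in.
#'
#' @param fields List of [bead_field()]s.
#' @param channel `"fda"` or `"pi"`.
#' @param k MAD multiplier of the background ceiling.
#' @return Integer threshold, with attribute `per_field` (the per-field
#'   integer thresholds, `NA` for excluded fields).
#' @export
fit_low_threshold <- function(fields, channel = c("fda", "pi"), k = 3) {
  channel <- match.arg(channel)
  if (inherits(fields, "bead_field")) fields <- list(fields)
  if (!length(fields)) stop_param("at least one field is required")
  if (length(fields) < 10)
    warning(sprintf(
      "only %d field(s) supplied; the validated protocol averages 10 images of 40-60 beads",
      length(fields)), call. = FALSE)
  per <- rep(NA_integer_, length(fields))
  for (i in seq_along(fields)) {
    px <- fields[[i]][[channel]]$pixels
    regs <- cell_regions(fields[[i]], channel)
    if (!length(regs)) {
      warning(sprintf("field %d: no detectable cells in %s channel; excluded",
                      i, channel), call. = FALSE)
      next
    }
    t0 <- floor(background_ceiling(px, k)) + 1L
    if (t0 > 255 ||
        !all(vapply(regs, function(r) max(px[r]) >= t0, TRUE))) {
      warning(sprintf(
        "field %d: cells not separable from background in %s channel; excluded",
        i, channel), call. = FALSE)
      next
    }
    per[i] <- as.integer(t0)
  }
  if (all(is.na(per)))
    stop_calibration("no usable calibration field for channel %s", channel)
  out <- as.integer(round_half_up(mean(per, na.rm = TRUE)))
  attr(out, "per_field") <- per
  out
}

# 256-bin grey-level histogram of a pixel grid.
grey_hist <- function(px) tabulate(as.integer(round(px)) + 1L, nbins = 256L)

# Mean per-cell sum intensity of one channel over fields, for every
# candidate threshold 0..255 at once (cumulative sums over the histogram).
per_cell_response_curve <- function(fields, channel, cells) {
  acc <- numeric(256)
  for (i in seq_along(fields)) {
    h <- grey_hist(fields[[i]][[channel]]$pixels)
    w <- h * (0:255)
    s_from <- rev(cumsum(rev(w)))   # s_from[t+1] = sum of grey >= t
    acc <- acc + s_from / cells[i]
  }
  acc / length(fields)
}

#' Match the PI set-up to the FDA set-up (signal equivalence)
#'
#' The viability formula is only valid when an equal number of dead and
#' viable cells provide the same signal. This routine chooses the PI
#' exposure time and PI low threshold such that the mean PI sum intensity
#' per cell measured on fully killed control fields matches the mean FDA
#' sum intensity per cell on fully live fields, within `tolerance`
#' (default 5%).
#'
#' @param dead_fields Killed-control fields (0% viability), acquired at the
#'   candidate PI exposures; cell counts come from ground truth (synthetic)
#'   or `dead_cell_counts`.
#' @param live_fields Fully live fields (~100% viability) at the chosen FDA
#'   exposure.
#' @param pi_candidates Candidate PI exposures (ms).
#' @param tolerance Relative mismatch accepted between per-cell signals.
#' @param live_cell_counts,dead_cell_counts Optional per-field cell counts
#'   overriding ground truth (matched aliquots of known cell number).
#' @return A [calibration_config()] with attribute `mismatch` (the achieved
#'   relative mismatch). Raises a calibration failure reporting the best
#'   achievable mismatch when no candidate reaches `tolerance`.
#' @export
match_pi_setup <- function(dead_fields, live_fields, pi_candidates,
                           tolerance = 0.05,
                           live_cell_counts = NULL, dead_cell_counts = NULL) {
  if (inherits(dead_fields, "bead_field")) dead_fields <- list(dead_fields)
  if (inherits(live_fields, "bead_field")) live_fields <- list(live_fields)
  if (!length(pi_candidates)) stop_param("pi_candidates must be non-empty")
  counts_of <- function(fields, which, given) {
    if (!is.null(given)) return(given)
    vapply(fields, function(f) {
      if (is.null(f$truth)) stop_param(
        "cell counts unavailable: supply ground truth or explicit counts")
      sum(f$truth$beads[[which]])
    }, 1)
  }
  n_live <- counts_of(live_fields, "n_live", live_cell_counts)
  n_dead <- counts_of(dead_fields, "n_dead", dead_cell_counts)
  if (any(n_live <= 0) || any(n_dead <= 0))
    stop_param("live/dead control fields must contain cells")

  exposure_fda <- unique(vapply(live_fields, function(f) f$fda$exposure_ms, 1))
  if (length(exposure_fda) != 1)
    stop_param("live fields must share one FDA exposure")
  low_fda <- fit_low_threshold(live_fields, "fda")
  ref <- mean(vapply(seq_along(live_fields), function(i)
    sum_intensity(live_fields[[i]]$fda, low_fda)$value / n_live[i], 1))

  expos <- vapply(dead_fields, function(f) f$pi$exposure_ms, 1)
  cands <- lapply(sort(pi_candidates), function(e) {
    idx <- which(expos == e)
    if (!length(idx))
      stop_param("no killed-control field acquired at PI exposure %g ms", e)
    flds <- dead_fields[idx]
    t0 <- fit_low_threshold(flds, "pi")
    curve <- per_cell_response_curve(flds, "pi", n_dead[idx])
    ts <- t0:255
    mm <- abs(curve[ts + 1L] - ref) / ref
    jbest <- which.min(mm)
    list(exposure = e, low = as.integer(ts[jbest]), mismatch = mm[jbest],
         elevation = ts[jbest] - as.integer(t0))
  })
  # an over-bright exposure can always be thresholded down to match, but
  # only by selecting very few pixels; among candidates reaching the
  # tolerance, prefer the one needing the least threshold elevation above
  # its fitted background level, then the shorter exposure
  feas <- Filter(function(c) c$mismatch <= tolerance, cands)
  best <- if (length(feas)) {
    feas[[order(vapply(feas, `[[`, 1, "elevation"),
                vapply(feas, `[[`, 1, "exposure"))[1]]]
  } else {
    cands[[which.min(vapply(cands, `[[`, 1, "mismatch"))]]
  }
  if (best$mismatch > tolerance)
    stop_calibration(
      "no PI exposure/threshold matches the FDA per-cell signal within %.1f%% (best achievable mismatch %.1f%% at %g ms, low %d)",
      100 * tolerance, 100 * best$mismatch, best$exposure, best$low,
      data = best)
  cfg <- calibration_config(low_fda = low_fda, low_pi = best$low,
                            exposure_fda_ms = exposure_fda,
                            exposure_pi_ms = best$exposure)
  attr(cfg, "mismatch") <- best$mismatch
  cfg
}

#' Check for overspill between the green and red filters
#'
#' On fields with single-channel-only content (all-live or all-dead
#' controls), any above-threshold, background-corrected signal appearing in
#' the other channel is optical overspill. Fractions are the wrong-channel
#' signal over the content-channel signal, pooled across fields; `0/0` (an
#' empty field) is reported as 0. The check passes when both directions are
#' below `limit` (default 1%; the validated filter set showed none).
#'
#' @param fields List of [bead_field()]s, each all-live, all-dead, or empty
#'   (mixed fields are rejected).
#' @param low_fda,low_pi Low thresholds; when `NULL`, fitted from the
#'   fields that carry content in that channel (the other channel's fitted
#'   value is reused when a channel has no fittable content).
#' @param limit Pass/fail limit on both fractions.
#' @return List of class `overspill_report`: `fda_into_pi`, `pi_into_fda`,
#'   `pass`, `limit`, and the thresholds used.
#' @export
check_overspill <- function(fields, low_fda = NULL, low_pi = NULL,
                            limit = 0.01) {
  if (inherits(fields, "bead_field")) fields <- list(fields)
  kind <- vapply(fields, function(f) {
    if (is.null(f$truth)) stop_param("overspill check requires ground truth")
    nl <- sum(f$truth$beads$n_live); nd <- sum(f$truth$beads$n_dead)
    if (nl > 0 && nd > 0) stop_param(
      "field with mixed live/dead content: overspill needs single-channel-only fields")
    if (nl > 0) "live" else if (nd > 0) "dead" else "empty"
  }, "")
  if (is.null(low_fda) && any(kind == "live"))
    low_fda <- suppressWarnings(fit_low_threshold(fields[kind == "live"], "fda"))
  if (is.null(low_pi) && any(kind == "dead"))
    low_pi <- suppressWarnings(fit_low_threshold(fields[kind == "dead"], "pi"))
  if (is.null(low_fda)) low_fda <- if (!is.null(low_pi)) low_pi else 41L
  if (is.null(low_pi)) low_pi <- low_fda

  corrected_sum <- function(px, low) {
    v <- as.integer(round(px))
    bg <- which.max(tabulate(v + 1L, nbins = 256L)) - 1L
    sel <- px >= low
    sum(pmax(px[sel] - bg, 0))
  }
  right_f <- wrong_f <- right_p <- wrong_p <- 0
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (kind[i] == "live") {
      right_f <- right_f + corrected_sum(f$fda$pixels, low_fda)
      wrong_f <- wrong_f + corrected_sum(f$pi$pixels, low_pi)
    } else if (kind[i] == "dead") {
      right_p <- right_p + corrected_sum(f$pi$pixels, low_pi)
      wrong_p <- wrong_p + corrected_sum(f$fda$pixels, low_fda)
    }
  }
  ratio <- function(wrong, right)
    if (right == 0) { if (wrong == 0) 0 else Inf } else wrong / right
  fda_into_pi <- ratio(wrong_f, right_f)
  pi_into_fda <- ratio(wrong_p, right_p)
  structure(list(fda_into_pi = fda_into_pi, pi_into_fda = pi_into_fda,
                 pass = fda_into_pi < limit && pi_into_fda < limit,
                 limit = limit, low_fda = low_fda, low_pi = low_pi),
            class = "overspill_report")
}

#' @export
print.overspill_report <- function(x, ...) {
  cat(sprintf("<overspill_report> FDA->PI %.4f | PI->FDA %.4f | limit %.3f | %s\n",
              x$fda_into_pi, x$pi_into_fda, x$limit,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
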