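#' Construct a single-channel fluorescence image
#'
#' An 8-bit grayscale micrograph of one fluorescence channel together with
#' its acquisition metadata. Pixel grey levels run 0-255; the exposure time
#' is carried because the per-cell signal of both dyes scales linearly with
#' it and calibration reasons in those terms.
#'
#' @param pixels Numeric matrix of grey levels in `[0, 255]` (rows = image
#'   rows). Integer-valued under the default acquisition model; non-integer
#'   grids are accepted for diagnostic (unquantised) renderings.
#' @param channel `"fda"` (live stain, green) or `"pi"` (dead stain, red).
#' @param exposure_ms Exposure time in milliseconds (> 0).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return An object of class `channel_image`.
#' @seealso [bead_field()], [sum_intensity()]
#' @export
channel_image <- function(pixels, channel = c("fda", "pi"), exposure_ms,
                          pixel_size_um) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_param("pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop_param("pixel values must lie in [0, 255]")
  if (!is_scalar_number(exposure_ms) || exposure_ms <= 0)
    stop_param("exposure_ms must be a positive number")
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0)
    stop_param("pixel_size_um must be a positive number")
  structure(list(pixels = pixels, channel = channel,
                 exposure_ms = exposure_ms, pixel_size_um = pixel_size_um),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %dx%d px  %.3g um/px  exposure %g ms\n",
              toupper(x$channel), nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, x$exposure_ms))
  invisible(x)
}

#' Construct a registered FDA/PI image pair of one microscope field
#'
#' @param fda,pi [channel_image()] objects of identical dimensions and pixel
#'   size (the two channels are acquired of the same field without moving the
#'   stage, so they are registered by construction).
#' @param truth Optional ground truth as produced by [generate_bead_field()]:
#'   a list with a per-bead table (`beads`), the cell density in the beads
#'   (`cells_per_ml_beads`) and the field-level `viability_fraction`.
#' @return An object of class `bead_field`.
#' @export
bead_field <- function(fda, pi, truth = NULL) {
  if (!inherits(fda, "channel_image") || !inherits(pi, "channel_image"))
    stop_param("fda and pi must be channel_image objects")
  if (fda$channel != "fda" || pi$channel != "pi")
    stop_param("channel metadata does not match the fda/pi slots")
  if (!identical(dim(fda$pixels), dim(pi$pixels)))
    stop_input("fda and pi images must have identical dimensions")
  if (fda$pixel_size_um != pi$pixel_size_um)
    stop_input("fda and pi images must share pixel_size_um")
  structure(list(fda = fda, pi = pi, truth = truth), class = "bead_field")
}

#' @export
print.bead_field <- function(x, ...) {
  cat(sprintf("<bead_field> %dx%d px, %.3g um/px\n",
              nrow(x$fda$pixels), ncol(x$fda$pixels), x$fda$pixel_size_um))
  cat(sprintf("  FDA exposure %g ms | PI exposure %g ms\n",
              x$fda$exposure_ms, x$pi$exposure_ms))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %d beads, %.3g cells/mL beads, viability %.1f%%\n",
                nrow(x$truth$beads), x$truth$cells_per_ml_beads,
                100 * x$truth$viability_fraction))
  }
  invisible(x)
}

#' Display the two channels of a bead field
#'
#' Renders the FDA (left) and PI (right) channels side by side as grey-level
#' rasters, for quick visual inspection of synthetic or imported fields.
#'
#' @param x A [bead_field()].
#' @param ... Ignored.
#' @export
plot.bead_field <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (ch in c("fda", "pi")) {
    px <- x[[ch]]$pixels / 255
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = ncol(px) / nrow(px))
    graphics::rasterImage(grDevices::as.raster(px), 0, 0, 1, 1)
    graphics::title(main = sprintf("%s (%g ms)", toupper(ch), x[[ch]]$exposure_ms))
  }
  invisible(x)
}

#' Calibration configuration for the two-channel sum-intensity assay
#'
#' Holds the low thresholds and exposure times that make an equal number of
#' live and dead cells yield the same sum intensity in the FDA and PI
#' channels, which the viability formula requires. The high threshold is
#' fixed at the 8-bit maximum of 255.
#'
#' @param low_fda,low_pi Integer low thresholds in `[0, 255]`.
#' @param exposure_fda_ms,exposure_pi_ms Exposure times in milliseconds.
#' @param high High threshold; fixed at 255.
#' @return An object of class `calibration_config`.
#' @seealso [default_calibration()], [match_pi_setup()]
#' @export
calibration_config <- function(low_fda, low_pi, exposure_fda_ms,
                               exposure_pi_ms, high = 255L) {
  for (v in list(low_fda, low_pi))
    if (!is_scalar_number(v) || v < 0 || v > 255 || v != round(v))
      stop_param("low thresholds must be integers in [0, 255]")
  if (!identical(as.integer(high), 255L))
    stop_param("the high threshold is fixed at 255")
  for (v in list(exposure_fda_ms, exposure_pi_ms))
    if (!is_scalar_number(v) || v <= 0)
      stop_param("exposure times must be positive")
  structure(list(low_fda = as.integer(low_fda), low_pi = as.integer(low_pi),
                 high = 255L,
                 exposure_fda_ms = exposure_fda_ms,
                 exposure_pi_ms = exposure_pi_ms),
            class = "calibration_config")
}

#' Shipped default calibration
#'
#' The documented defaults when no calibration images are supplied: a low
#' threshold of 41 for both channels with exposures of 150 ms (FDA) and
#' 1000 ms (PI), the values validated for alginate-encapsulated HepG2
#' spheroids on the original set-up. They are appropriate starting points
#' only; recalibrate with [fit_low_threshold()] and [match_pi_setup()] for
#' any new optical configuration.
#'
#' @return A [calibration_config()].
#' @export
default_calibration <- function() {
  calibration_config(low_fda = 41L, low_pi = 41L,
                     exposure_fda_ms = 150, exposure_pi_ms = 1000)
}

#' @export
print.calibration_config <- function(x, ...) {
  cat("<calibration_config>\n")
  cat(sprintf("  FDA: low %d, high 255, exposure %g ms\n",
              x$low_fda, x$exposure_fda_ms))
  cat(sprintf("  PI : low %d, high 255, exposure %g ms\n",
              x$low_pi, x$exposure_pi_ms))
  mm <- attr(x, "mismatch")
  if (!is.null(mm))
    cat(sprintf("  matched signal mismatch: %.2f%%\n", 100 * mm))
  invisible(x)
}
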