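# File formats: 8-bit grayscale TIFF per channel with a JSON sidecar
# carrying acquisition metadata (and ground truth for synthetic fields);
# CSV for process logs and concentration series; JSON for calibration.
#
# Filename convention: <field>_<channel>_<exposure>ms.tif. A sidecar JSON
# always overrides filename parsing.

#' Write a bead field to disk (TIFF pair + JSON sidecar)
#'
#' @param field A [bead_field()] with integer pixel grids.
#' @param dir Output directory (created if needed).
#' @param prefix Field name used in the filenames.
#' @return Invisibly, the three paths written (`fda`, `pi`, `sidecar`).
#' @export
write_bead_field <- function(field, dir, prefix = "field1") {
  if (!inherits(field, "bead_field")) stop_param("field must be a bead_field")
  for (ch in c("fda", "pi"))
    if (any(field[[ch]]$pixels != round(field[[ch]]$pixels)))
      stop_input("non-integer pixel grid: 8-bit TIFF requires integer grey levels")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ch in c("fda", "pi")) {
    ci <- field[[ch]]
    p <- file.path(dir, sprintf("%s_%s_%gms.tif", prefix, ch, ci$exposure_ms))
    tiff::writeTIFF(ci$pixels / 255, p, bits.per.sample = 8L,
                    compression = "none")
    paths[[ch]] <- p
  }
  meta <- list(
    channels = list(
      fda = list(file = basename(paths$fda),
                 exposure_ms = field$fda$exposure_ms,
                 pixel_size_um = field$fda$pixel_size_um),
      pi = list(file = basename(paths$pi),
                exposure_ms = field$pi$exposure_ms,
                pixel_size_um = field$pi$pixel_size_um)),
    truth = field$truth
  )
  sc <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(meta, sc, auto_unbox = TRUE, digits = NA, null = "null")
  paths$sidecar <- sc
  invisible(paths)
}

read_tiff_8bit <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                 error = function(e) stop_input("unreadable TIFF: %s (%s)",
                                                path, conditionMessage(e)))
  bits <- attr(px, "bits.per.sample")
  if (!is.null(bits) && bits != 8L)
    stop_input("unsupported bit depth (%d-bit) in %s: only 8-bit grayscale is read, no silent rescale",
               bits, path)
  if (length(dim(px)) == 3L)
    stop_input("multi-channel TIFF in %s: one grayscale image per channel is required", path)
  storage.mode(px) <- "double"
  attributes(px) <- list(dim = dim(px))
  px
}

parse_channel_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("_(fda|pi)_([0-9.]+)ms\\.tiff?$", basename(path),
                          ignore.case = TRUE))[[1]]
  if (length(m) != 3) return(NULL)
  list(channel = tolower(m[2]), exposure_ms = as.numeric(m[3]))
}

#' Read a bead field from a TIFF pair (and optional sidecar)
#'
#' Exposure metadata comes from the sidecar when given, otherwise from the
#' `<field>_<channel>_<exposure>ms.tif` filename convention; missing
#' exposure metadata is an error (sum-intensity calibration is meaningless
#' without it). Only single-plane 8-bit grayscale TIFFs are accepted.
#'
#' @param fda_path,pi_path Paths to the two channel TIFFs.
#' @param sidecar_path Optional JSON sidecar written by
#'   [write_bead_field()]; when present it also restores ground truth.
#' @param pixel_size_um Pixel size fallback when no sidecar is given.
#' @return A [bead_field()].
#' @export
read_bead_field <- function(fda_path, pi_path, sidecar_path = NULL,
                            pixel_size_um = 4) {
  fpx <- read_tiff_8bit(fda_path)
  ppx <- read_tiff_8bit(pi_path)
  if (!identical(dim(fpx), dim(ppx)))
    stop_input("dimension mismatch between %s and %s", fda_path, pi_path)
  truth <- NULL
  if (!is.null(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    exp_f <- meta$channels$fda$exposure_ms
    exp_p <- meta$channels$pi$exposure_ms
    psz <- meta$channels$fda$pixel_size_um
    if (!is.null(meta$truth)) {
      truth <- meta$truth
      truth$beads <- as.data.frame(truth$beads)
      truth$beads$bead <- as.integer(truth$beads$bead)
      truth$beads$n_live <- as.integer(truth$beads$n_live)
      truth$beads$n_dead <- as.integer(truth$beads$n_dead)
      if (!is.null(truth$seed)) truth$seed <- as.integer(truth$seed)
    }
  } else {
    mf <- parse_channel_filename(fda_path)
    mp <- parse_channel_filename(pi_path)
    exp_f <- mf$exposure_ms
    exp_p <- mp$exposure_ms
    psz <- pixel_size_um
  }
  if (is.null(exp_f) || is.null(exp_p) || is.na(exp_f) || is.na(exp_p))
    stop_input("missing exposure metadata: provide a sidecar or use the <field>_<channel>_<exposure>ms.tif naming convention")
  bead_field(channel_image(fpx, "fda", exp_f, psz),
             channel_image(ppx, "pi", exp_p, psz),
             truth = truth)
}

#' Write / read a calibration configuration as JSON
#'
#' @param config A [calibration_config()].
#' @param path Output path.
#' @return `write_calibration()` returns the path invisibly;
#'   `read_calibration()` returns a [calibration_config()].
#' @export
write_calibration <- function(config, path) {
  if (!inherits(config, "calibration_config"))
    stop_param("config must be a calibration_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_config(low_fda = x$low_fda, low_pi = x$low_pi,
                     exposure_fda_ms = x$exposure_fda_ms,
                     exposure_pi_ms = x$exposure_pi_ms)
}

#' Read a bioreactor process log from CSV
#'
#' Expected header (documented convention): `time_h, glucose_mM,
#' lactate_mM, do_sub_pct, do_post_pct, flow_mL_min`, optionally
#' `cell_count, biomass_volume_L, media_volume_L`. Time must be strictly
#' increasing; concentrations and flow non-negative.
#'
#' @param path CSV path.
#' @return Data frame of class `process_log`.
#' @export
read_process_log <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "glucose_mM", "lactate_mM", "do_sub_pct",
            "do_post_pct", "flow_mL_min")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("process log %s lacks column(s): %s", path,
               paste(miss, collapse = ", "))
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop_input("time_h must be strictly increasing")
  if (any(df$glucose_mM < 0) || any(df$lactate_mM < 0))
    stop_input("concentrations must be non-negative")
  if (any(df$flow_mL_min < 0)) stop_input("flow must be non-negative")
  class(df) <- c("process_log", "data.frame")
  df
}

#' Read a concentration time series from CSV
#'
#' Expected header: `time_h, conc, volume_L` (concentration units depend on
#' the analyte: umol/L for bilirubin, ng/mL for proteins).
#'
#' @param path CSV path.
#' @return Data frame of class `concentration_series`.
#' @export
read_concentration_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "conc", "volume_L")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("concentration series %s lacks column(s): %s", path,
               paste(miss, collapse = ", "))
  if (is.unsorted(df$time_h)) stop_input("time_h must be increasing")
  if (any(df$volume_L <= 0)) stop_input("volume_L must be positive")
  class(df) <- c("concentration_series", "data.frame")
  df
}
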