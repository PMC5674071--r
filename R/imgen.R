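#' Generator settings for synthetic bead fields
#'
#' Bundles and validates every knob of the synthetic dual-channel bead-field
#' generator. The defaults describe the assay's reference conditions:
#' alginate beads of 525.8 +/- 95 um diameter imaged at 4 um/px (a 525 um
#' bead spans ~130 px, the scale implied by a x4 objective), a bead-phase
#' cell density of 22 million cells per mL of beads (the high-density
#' calibration condition), FDA exposure 150 ms and PI exposure 1000 ms with
#' per-cell integrated responses chosen so the two channels match at those
#' exposures, a background of ~10 grey levels at the reference exposures,
#' and a camera read noise of 1.5 grey levels.
#'
#' @param n_beads Number of beads per field (>= 1).
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Pixel size, micrometres per pixel.
#' @param bead_diameter_mean_um,bead_diameter_sd_um Normal distribution of
#'   bead diameters, truncated below at 100 um.
#' @param cells_per_ml_beads Cell density per millilitre of bead volume.
#' @param viability_fraction Ground-truth live fraction in `[0, 1]`.
#' @param per_cell_intensity Named vector `c(fda=, pi=)`: integrated grey
#'   level contributed by one cell per millisecond of exposure (before
#'   clipping). The defaults satisfy `fda * 150 == pi * 1000`, i.e. the two
#'   dyes give equal per-cell signal at the reference exposures.
#' @param background_rate Named vector: background grey level per
#'   millisecond (fluorescent background scales with exposure).
#' @param background_offset Named vector: exposure-independent camera offset
#'   in grey levels (default 0).
#' @param noise_sd Gaussian read-noise standard deviation, grey levels.
#' @param exposure_ms Named vector of exposure times per channel.
#' @param blob_sigma_um Gaussian footprint (sd) of a single cell, ~one cell
#'   diameter.
#' @param placement `"spheroid"` (cells grouped in spheroid-like clusters,
#'   default) or `"uniform"` (cells scattered over the whole bead circle).
#' @param spheroid_cells Mean number of cells per spheroid cluster.
#' @param spheroid_sigma_um Spatial sd of cells around their cluster centre.
#' @param crosstalk_fda_to_pi,crosstalk_pi_to_fda Optical overspill:
#'   fraction of one channel's imaged cell signal leaking into the other
#'   channel's image. Default 0 (none observed on the validated set-up).
#' @param fda_density_response Optional function `f(cells_per_ml_beads)`
#'   returning a multiplier on the FDA per-cell response, to emulate the
#'   reduced FDA signal seen at very low cell densities; default `NULL`
#'   (no density dependence assumed).
#' @param integer_pixels Quantise pixels to 8-bit integers (default). Set
#'   `FALSE` for diagnostic renderings in which signal linearity is exact.
#' @return A validated list of class `gen_params`.
#' @seealso [generate_bead_field()]
#' @export
gen_params <- function(n_beads = 8L,
                       width_px = 640L, height_px = 640L,
                       pixel_size_um = 4,
                       bead_diameter_mean_um = 525.8,
                       bead_diameter_sd_um = 95,
                       cells_per_ml_beads = 22e6,
                       viability_fraction = 1,
                       per_cell_intensity = c(fda = 2.4, pi = 0.36),
                       background_rate = c(fda = 10 / 150, pi = 10 / 1000),
                       background_offset = c(fda = 0, pi = 0),
                       noise_sd = 1.5,
                       exposure_ms = c(fda = 150, pi = 1000),
                       blob_sigma_um = 15,
                       placement = c("spheroid", "uniform"),
                       spheroid_cells = 100,
                       spheroid_sigma_um = 25,
                       crosstalk_fda_to_pi = 0,
                       crosstalk_pi_to_fda = 0,
                       fda_density_response = NULL,
                       integer_pixels = TRUE) {
  placement <- match.arg(placement)
  if (!is_scalar_number(viability_fraction) ||
      viability_fraction < 0 || viability_fraction > 1)
    stop_param("viability_fraction must lie in [0, 1]")
  if (!is_scalar_number(n_beads) || n_beads < 1)
    stop_param("n_beads must be >= 1")
  for (nm in c("width_px", "height_px", "pixel_size_um",
               "bead_diameter_mean_um", "bead_diameter_sd_um",
               "cells_per_ml_beads", "blob_sigma_um",
               "spheroid_cells", "spheroid_sigma_um")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0)
      stop_param("%s must be a positive number", nm)
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop_param("noise_sd must be >= 0")
  for (nm in c("per_cell_intensity", "background_rate", "background_offset",
               "exposure_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(c("fda", "pi") %in% names(v)))
      stop_param("%s must be a named vector with entries 'fda' and 'pi'", nm)
  }
  if (any(exposure_ms <= 0)) stop_param("exposure times must be positive")
  for (ct in c(crosstalk_fda_to_pi, crosstalk_pi_to_fda))
    if (!is_scalar_number(ct) || ct < 0 || ct > 1)
      stop_param("crosstalk fractions must lie in [0, 1]")
  if (!is.null(fda_density_response) && !is.function(fda_density_response))
    stop_param("fda_density_response must be NULL or a function")
  structure(as.list(environment()), class = "gen_params")
}

# Bead volume in mL from a diameter in micrometres (1 mL = 1e12 um^3).
bead_volume_ml <- function(diameter_um) (4 / 3) * pi * (diameter_um / 2)^3 * 1e-12

# Sample bead geometry (consumes the active RNG stream).
sample_bead_geometry <- function(p) {
  r_max_px <- 0
  d <- numeric(p$n_beads)
  for (i in seq_len(p$n_beads)) {
    repeat {
      di <- stats::rnorm(1, p$bead_diameter_mean_um, p$bead_diameter_sd_um)
      if (di >= 100) break
    }
    d[i] <- di
  }
  r_px <- d / 2 / p$pixel_size_um
  # beads stay a full blob-kernel half-width clear of the image border so
  # every cell's rendered footprint lies wholly inside the image (keeps the
  # total signal exactly proportional to the cell count)
  margin <- ceiling(4 * p$blob_sigma_um / p$pixel_size_um) + 2
  if (2 * (max(r_px) + margin) > min(p$width_px, p$height_px))
    stop_param("image too small for the sampled bead diameters")
  x <- y <- numeric(p$n_beads)
  for (i in seq_len(p$n_beads)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      xi <- stats::runif(1, r_px[i] + margin, p$width_px - r_px[i] - margin)
      yi <- stats::runif(1, r_px[i] + margin, p$height_px - r_px[i] - margin)
      if (i == 1L ||
          all(sqrt((x[seq_len(i - 1)] - xi)^2 + (y[seq_len(i - 1)] - yi)^2) >
              r_px[seq_len(i - 1)] + r_px[i] + 2)) {
        x[i] <- xi; y[i] <- yi; placed <- TRUE; break
      }
    }
    if (!placed)
      stop_param("could not place %d non-overlapping beads in a %dx%d field",
                 p$n_beads, p$width_px, p$height_px)
  }
  data.frame(bead = seq_len(p$n_beads), center_x_px = x, center_y_px = y,
             diameter_um = d)
}

# Assign live/dead cell counts to beads by largest-remainder apportionment so
# the field total and the field live total are hit exactly.
assign_cell_counts <- function(beads, p) {
  vol <- bead_volume_ml(beads$diameter_um)
  total <- as.integer(round(p$cells_per_ml_beads * sum(vol)))
  n <- apportion(total, vol)
  n_live <- apportion(as.integer(round(p$viability_fraction * total)), n)
  beads$n_live <- pmin(n_live, n)
  beads$n_dead <- n - beads$n_live
  beads
}

# Cell centres for one bead (consumes the active RNG stream). Returns integer
# pixel coordinates and a live/dead flag.
place_cells <- function(bead, p) {
  n <- bead$n_live + bead$n_dead
  if (n == 0L) return(NULL)
  r_px <- bead$diameter_um / 2 / p$pixel_size_um
  if (p$placement == "uniform") {
    rr <- (r_px - 1) * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cx <- bead$center_x_px + rr * cos(th)
    cy <- bead$center_y_px + rr * sin(th)
  } else {
    k <- max(1L, as.integer(round(n / p$spheroid_cells)))
    sp_sigma_px <- p$spheroid_sigma_um / p$pixel_size_um
    # spheroids occupy the full bead volume (growth is uniform across the
    # bead), so cluster centres may sit close to the boundary; cells are
    # resampled below to stay inside the bead circle
    c_max <- max(r_px - sp_sigma_px, 0.3 * r_px)
    rr <- c_max * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    kx <- bead$center_x_px + rr * cos(th)
    ky <- bead$center_y_px + rr * sin(th)
    cl <- sample.int(k, n, replace = TRUE)
    cx <- kx[cl] + stats::rnorm(n, 0, sp_sigma_px)
    cy <- ky[cl] + stats::rnorm(n, 0, sp_sigma_px)
    # keep every cell inside its bead: resample stragglers, clamp as a last
    # resort so the loop is bounded
    for (iter in 1:50) {
      bad <- (cx - bead$center_x_px)^2 + (cy - bead$center_y_px)^2 > (r_px - 1)^2
      if (!any(bad)) break
      nb <- sum(bad)
      cx[bad] <- kx[cl[bad]] + stats::rnorm(nb, 0, sp_sigma_px)
      cy[bad] <- ky[cl[bad]] + stats::rnorm(nb, 0, sp_sigma_px)
    }
    bad <- (cx - bead$center_x_px)^2 + (cy - bead$center_y_px)^2 > (r_px - 1)^2
    if (any(bad)) {
      sc <- (r_px - 1) / sqrt((cx[bad] - bead$center_x_px)^2 +
                                (cy[bad] - bead$center_y_px)^2)
      cx[bad] <- bead$center_x_px + (cx[bad] - bead$center_x_px) * sc
      cy[bad] <- bead$center_y_px + (cy[bad] - bead$center_y_px) * sc
    }
  }
  alive <- rep(FALSE, n)
  if (bead$n_live > 0L) alive[sample.int(n, bead$n_live)] <- TRUE
  data.frame(x = pmin(pmax(round(cx), 1), p$width_px),
             y = pmin(pmax(round(cy), 1), p$height_px),
             alive = alive)
}

gaussian_kernel <- function(sigma_px) {
  half <- ceiling(4 * sigma_px)
  ax <- (-half):half
  k <- outer(exp(-ax^2 / (2 * sigma_px^2)), exp(-ax^2 / (2 * sigma_px^2)))
  k / sum(k)
}

# Spatial blob field of unit-integral cells at the given integer positions.
blob_field <- function(xs, ys, p) {
  counts <- matrix(tabulate((xs - 1) * p$height_px + ys,
                            nbins = p$height_px * p$width_px),
                   nrow = p$height_px, ncol = p$width_px)
  if (sum(counts) == 0) return(counts)
  k <- gaussian_kernel(p$blob_sigma_um / p$pixel_size_um)
  EBImage::filter2(counts, k, boundary = 0)
}

#' Generate a synthetic dual-channel bead field with known ground truth
#'
#' Simulates one microscope field of alginate beads containing live and dead
#' cells. Live cells contribute fluorescence only to the FDA channel and
#' dead cells only to the PI channel; the per-cell signal and the
#' fluorescent background both scale linearly with exposure time, after
#' which Gaussian read noise is added and pixels are clipped to the 8-bit
#' range. The returned ground truth records every bead's position, diameter
#' and live/dead composition, so calibration and quantification can be
#' benchmarked without real micrographs.
#'
#' Generation is a pure function of `(params, seed)`: the same inputs yield
#' bit-identical images. Geometry (beads, cells) and noise use separate
#' sub-streams derived from the seed, so the geometry is unchanged when only
#' `noise_sd` differs.
#'
#' @param params A [gen_params()] settings object.
#' @param seed Integer seed.
#' @param exposure_ms Optional named vector overriding the exposures in
#'   `params` (convenient for acquiring the same field at several candidate
#'   exposures, as exposure selection requires).
#' @return A [bead_field()] whose `truth` lists every bead.
#' @examples
#' f <- generate_bead_field(gen_params(n_beads = 2, width_px = 320,
#'                                     height_px = 320), seed = 1)
#' f$truth$viability_fraction
#' @export
generate_bead_field <- function(params = gen_params(), seed,
                                exposure_ms = NULL) {
  if (!inherits(params, "gen_params")) stop_param("params must come from gen_params()")
  if (!is_scalar_number(seed)) stop_param("seed must be a single integer")
  if (!is.null(exposure_ms)) {
    params$exposure_ms[names(exposure_ms)] <- exposure_ms
  }
  with_seed(as.integer(seed) %% 2147483647L, {
    s_geom <- sample.int(2147483646L, 1)
    s_noise <- sample.int(2147483646L, 1)
    set.seed(s_geom)
    beads <- assign_cell_counts(sample_bead_geometry(params), params)
    render_field_impl(beads, params, s_noise, seed)
  })
}

#' Render a bead field from an explicit bead table
#'
#' Lower-level companion of [generate_bead_field()] for tests and controlled
#' scenes (e.g. a deliberately touching bead pair): bead centres, diameters
#' and live/dead counts are supplied rather than sampled.
#'
#' @param beads Data frame with columns `center_x_px`, `center_y_px`,
#'   `diameter_um`, `n_live`, `n_dead`.
#' @param params A [gen_params()] object (its `n_beads`,
#'   `bead_diameter_*` and `viability_fraction` entries are ignored).
#' @param seed Integer seed for cell placement and noise.
#' @return A [bead_field()].
#' @export
render_bead_field <- function(beads, params = gen_params(), seed) {
  need <- c("center_x_px", "center_y_px", "diameter_um", "n_live", "n_dead")
  if (!is.data.frame(beads) || !all(need %in% names(beads)))
    stop_param("beads must be a data frame with columns %s",
               paste(need, collapse = ", "))
  if (any(beads$n_live < 0) || any(beads$n_dead < 0) ||
      any(beads$diameter_um <= 0))
    stop_param("bead table violates its invariants")
  beads$bead <- seq_len(nrow(beads))
  with_seed(as.integer(seed) %% 2147483647L, {
    s_geom <- sample.int(2147483646L, 1)
    s_noise <- sample.int(2147483646L, 1)
    set.seed(s_geom)
    render_field_impl(beads, params, s_noise, seed)
  })
}

render_field_impl <- function(beads, p, s_noise, seed) {
  cells <- do.call(rbind, lapply(seq_len(nrow(beads)), function(i)
    place_cells(beads[i, ], p)))
  if (is.null(cells)) cells <- data.frame(x = integer(), y = integer(),
                                          alive = logical())
  live_blobs <- blob_field(cells$x[cells$alive], cells$y[cells$alive], p)
  dead_blobs <- blob_field(cells$x[!cells$alive], cells$y[!cells$alive], p)

  fda_gain <- p$per_cell_intensity[["fda"]]
  if (!is.null(p$fda_density_response))
    fda_gain <- fda_gain * p$fda_density_response(p$cells_per_ml_beads)
  pi_gain <- p$per_cell_intensity[["pi"]]

  fda_signal <- live_blobs * fda_gain * p$exposure_ms[["fda"]]
  pi_signal <- dead_blobs * pi_gain * p$exposure_ms[["pi"]]
  # crosstalk is expressed as a fraction of the source channel's own imaged
  # cell signal appearing in the target channel
  pi_img <- pi_signal + p$crosstalk_fda_to_pi * fda_signal
  fda_img <- fda_signal + p$crosstalk_pi_to_fda * pi_signal

  fda_img <- fda_img + p$background_offset[["fda"]] +
    p$background_rate[["fda"]] * p$exposure_ms[["fda"]]
  pi_img <- pi_img + p$background_offset[["pi"]] +
    p$background_rate[["pi"]] * p$exposure_ms[["pi"]]

  set.seed(s_noise)
  if (p$noise_sd > 0) {
    n <- p$height_px * p$width_px
    fda_img <- fda_img + matrix(stats::rnorm(n, 0, p$noise_sd), p$height_px)
    pi_img <- pi_img + matrix(stats::rnorm(n, 0, p$noise_sd), p$height_px)
  }
  clipq <- function(m) {
    if (p$integer_pixels) m <- round(m)
    pmin(pmax(m, 0), 255)
  }
  total <- sum(beads$n_live) + sum(beads$n_dead)
  truth <- list(
    beads = beads[, c("bead", "center_x_px", "center_y_px", "diameter_um",
                      "n_live", "n_dead")],
    cells_per_ml_beads = total / sum(bead_volume_ml(beads$diameter_um)),
    viability_fraction = if (total > 0) sum(beads$n_live) / total else NA_real_,
    seed = as.integer(seed)
  )
  bead_field(
    channel_image(clipq(fda_img), "fda", p$exposure_ms[["fda"]], p$pixel_size_um),
    channel_image(clipq(pi_img), "pi", p$exposure_ms[["pi"]], p$pixel_size_um),
    truth = truth
  )
}

#' Apply a timed Me2SO lethal insult to a field's ground truth
#'
#' Models the graded killed-control preparation: exposing beads to 50%
#' (w/v) dimethyl sulfoxide for a chosen number of minutes converts live
#' cells to dead ones. Survival follows an exponential decay
#' `exp(-rate * minutes)`; the default rate of 0.35/min leaves under 1% of
#' cells alive after the 15-minute preset, i.e. a complete-kill control.
#' Total cell count is conserved, so the insulted truth can be re-rendered
#' with [render_bead_field()] to produce matched killed-control images.
#'
#' @param truth Ground truth from [generate_bead_field()].
#' @param minutes Insult duration in minutes (>= 0); the validated presets
#'   are 5, 10 and 15 but any duration is accepted.
#' @param rate Kill-rate constant per minute.
#' @return Ground truth with live cells converted to dead; viability is
#'   monotone non-increasing in `minutes`.
#' @export
apply_lethal_insult <- function(truth, minutes, rate = 0.35) {
  if (!is_scalar_number(minutes) || minutes < 0)
    stop_param("minutes must be a non-negative number")
  if (!is_scalar_number(rate) || rate < 0)
    stop_param("rate must be a non-negative number")
  if (minutes == 0) return(truth)
  b <- truth$beads
  total_live <- sum(b$n_live)
  keep <- apportion(as.integer(round(total_live * exp(-rate * minutes))),
                    b$n_live)
  b$n_dead <- b$n_dead + (b$n_live - keep)
  b$n_live <- keep
  truth$beads <- b
  total <- sum(b$n_live) + sum(b$n_dead)
  truth$viability_fraction <- if (total > 0) sum(b$n_live) / total else NA_real_
  truth
}
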