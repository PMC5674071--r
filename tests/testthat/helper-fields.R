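# Shared fixtures: small synthetic fields and a matched calibration, built
# once per test run.

tiny_params <- function(...) {
  gen_params(n_beads = 2, width_px = 352, height_px = 352, ...)
}

small_params <- function(...) {
  gen_params(n_beads = 4, width_px = 512, height_px = 512, ...)
}

# A manually constructed field: uniform background with rectangular "cell"
# patches, plus a truth table marking one bead per patch. Used for oracle
# tests where analytic control over every pixel matters.
patch_field <- function(bg = 10, patches = list(list(x = 40:60, y = 40:60, level = 60)),
                        size = 128L, noise_sd = 0, pixel_size_um = 4) {
  mk <- function(levels) {
    px <- matrix(bg, size, size)
    for (i in seq_along(patches)) {
      p <- patches[[i]]
      px[p$y, p$x] <- levels[i]
    }
    if (noise_sd > 0)
      px <- pmin(pmax(px + round(matrix(stats::rnorm(size^2, 0, noise_sd),
                                        size)), 0), 255)
    px
  }
  lv <- vapply(patches, function(p) p$level, 1)
  beads <- data.frame(
    bead = seq_along(patches),
    center_x_px = vapply(patches, function(p) mean(p$x), 1),
    center_y_px = vapply(patches, function(p) mean(p$y), 1),
    diameter_um = vapply(patches, function(p)
      (max(length(p$x), length(p$y)) + 4) * pixel_size_um, 1),
    n_live = 50L, n_dead = 50L)
  truth <- list(beads = beads, cells_per_ml_beads = NA_real_,
                viability_fraction = 0.5)
  bead_field(channel_image(mk(lv), "fda", 150, pixel_size_um),
             channel_image(mk(lv), "pi", 1000, pixel_size_um),
             truth = truth)
}

# Matched calibration built from small live/dead control sets; cached so the
# many tests that need a realistic config do not refit it.
matched_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) {
      live <- lapply(1:3, function(s) generate_bead_field(small_params(), seed = s))
      pdead <- small_params(viability_fraction = 0)
      dead <- lapply(c(600, 800, 1000, 2000), function(e)
        generate_bead_field(pdead, seed = 11, exposure_ms = c(pi = e)))
      cfg <<- suppressWarnings(
        match_pi_setup(dead, live, c(600, 800, 1000, 2000)))
    }
    cfg
  }
})

expect_param_error <- function(expr) expect_error(expr, class = "bv_parameter_error")
expect_input_error <- function(expr) expect_error(expr, class = "bv_input_error")
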