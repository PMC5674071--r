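test_that("select_exposure returns a single unsaturated candidate unchanged", {
  f <- generate_bead_field(tiny_params(), seed = 1)
  sel <- select_exposure(list(f), "fda", candidates = 150)
  expect_equal(sel$exposure_ms, 150)
  expect_false(sel$reports$excluded)
})

test_that("in the noiseless unclipped limit SNR is exposure-invariant and ties go short", {
  p <- tiny_params(noise_sd = 0, integer_pixels = FALSE,
                   per_cell_intensity = c(fda = 1.2, pi = 0.18))
  cands <- c(100, 150, 200)
  flds <- lapply(cands, function(e)
    generate_bead_field(p, seed = 6, exposure_ms = c(fda = e)))
  expect_true(all(vapply(flds, function(f) max(f$fda$pixels) < 255, TRUE)))
  sel <- select_exposure(flds, "fda", cands)
  snr <- sel$reports$snr
  expect_lt(diff(range(snr)) / mean(snr), 1e-6)  # closed form: both sums scale with exposure
  expect_equal(sel$exposure_ms, 100)             # tie rule: shortest wins
})

test_that("saturated candidates are excluded; an interior optimum emerges under clipping", {
  # bright configuration with a camera offset: SNR grows with exposure until
  # clipping, and exposures that saturate too much are excluded
  p <- gen_params(n_beads = 3, width_px = 384, height_px = 384,
                  per_cell_intensity = c(fda = 3.4, pi = 0.51),
                  background_offset = c(fda = 10, pi = 10), noise_sd = 1)
  cands <- c(100, 150, 200, 300, 400)
  flds <- lapply(cands, function(e)
    generate_bead_field(p, seed = 42, exposure_ms = c(fda = e)))
  sel <- select_exposure(flds, "fda", cands, max_saturated_fraction = 0.02)
  expect_equal(sel$exposure_ms, 150)   # the validated instrument's FDA choice
  expect_false(sel$reports$excluded[sel$reports$exposure_ms == 150])
  expect_true(any(sel$reports$excluded))
  # the chosen exposure never violates the saturation limit
  chosen <- sel$reports[sel$reports$exposure_ms == sel$exposure_ms, ]
  expect_lte(chosen$saturated_fraction, 0.02)
  # with an impossible limit every candidate is rejected
  expect_error(select_exposure(flds, "fda", cands, max_saturated_fraction = 0),
               class = "bv_calibration_error")
  expect_param_error(select_exposure(flds, "fda", numeric(0)))
})

test_that("per-field low threshold separates a uniform background from cells", {
  f <- patch_field(bg = 10, patches = list(list(x = 40:60, y = 40:60, level = 60)))
  thr <- suppressWarnings(fit_low_threshold(list(f), "fda"))
  expect_gt(thr, 10)
  expect_lte(thr, 60)
})

test_that("fit_low_threshold equals a brute-force 256-level scan averaged over fields", {
  set.seed(31)
  fields <- lapply(1:10, function(i) {
    bg <- sample(5:20, 1)
    patch_field(bg = bg, noise_sd = 2, patches = list(
      list(x = 20:35, y = 20:35, level = bg + sample(30:80, 1)),
      list(x = 70:95, y = 60:80, level = bg + sample(30:80, 1))))
  })
  got <- fit_low_threshold(fields, "fda")

  # independent oracle: scan all 256 levels per field for the smallest level
  # above the robust background that retains every cell region
  oracle_field <- function(f) {
    px <- f$fda$pixels
    v <- as.integer(round(px))
    m <- which.max(tabulate(v + 1L, nbins = 256L)) - 1L
    bg_ceiling <- m + 3 * stats::mad(v, center = m)
    regs <- lapply(seq_len(nrow(f$truth$beads)), function(i) {
      b <- f$truth$beads[i, ]
      r <- b$diameter_um / 2 / f$fda$pixel_size_um
      xs <- matrix(rep(seq_len(ncol(px)), each = nrow(px)), nrow(px))
      ys <- matrix(rep(seq_len(nrow(px)), ncol(px)), nrow(px))
      which((xs - b$center_x_px)^2 + (ys - b$center_y_px)^2 <= r^2)
    })
    for (t in 0:255) {
      if (t <= bg_ceiling) next
      if (all(vapply(regs, function(r) any(px[r] >= t), TRUE))) return(t)
    }
    NA_integer_
  }
  per <- vapply(fields, oracle_field, 1L)
  expect_equal(as.integer(got), as.integer(floor(mean(per) + 0.5)))
  expect_equal(as.integer(attr(got, "per_field")), per)
})

test_that("background-only fields are excluded from the threshold, not averaged", {
  fields <- lapply(1:3, function(s) generate_bead_field(tiny_params(), seed = s))
  base <- suppressWarnings(fit_low_threshold(fields, "fda"))
  empty <- generate_bead_field(tiny_params(viability_fraction = 0), seed = 9)
  with_empty <- suppressWarnings(fit_low_threshold(c(fields, list(empty)), "fda"))
  expect_equal(as.integer(with_empty), as.integer(base))
  dead_only <- generate_bead_field(tiny_params(viability_fraction = 0), seed = 10)
  expect_error(suppressWarnings(fit_low_threshold(list(dead_only), "fda")),
               class = "bv_calibration_error")
})

test_that("match_pi_setup recovers the matched PI exposure and transfers to mixed fields", {
  cfg <- matched_config()
  # the generator's per-cell responses are equal at FDA 150 ms / PI 1000 ms
  expect_equal(cfg$exposure_pi_ms, 1000)
  expect_equal(cfg$exposure_fda_ms, 150)
  expect_lte(attr(cfg, "mismatch"), 0.05)

  # independent check: under the chosen set-up the per-cell PI signal on
  # killed controls matches the per-cell FDA signal on live controls
  live <- lapply(1:3, function(s) generate_bead_field(small_params(), seed = s))
  pdead <- small_params(viability_fraction = 0)
  dead1000 <- generate_bead_field(pdead, seed = 11, exposure_ms = c(pi = 1000))
  ref <- mean(vapply(live, function(f)
    sum_intensity(f$fda, cfg$low_fda)$value / sum(f$truth$beads$n_live), 1))
  got <- sum_intensity(dead1000$pi, cfg$low_pi)$value /
    sum(dead1000$truth$beads$n_dead)
  expect_lt(abs(got - ref) / ref, 0.05)

  # transfer: a 50/50 field quantifies near 50% under the matched config
  f50 <- generate_bead_field(small_params(viability_fraction = 0.5), seed = 21)
  expect_lt(abs(suppressWarnings(quantify(f50, cfg))$percent - 50), 5)
})

test_that("identical per-cell responses in both channels give a symmetric set-up", {
  sym <- list(per_cell_intensity = c(fda = 2.4, pi = 2.4),
              background_rate = c(fda = 10 / 150, pi = 10 / 150))
  p <- do.call(small_params, sym)
  live <- lapply(1:2, function(s) generate_bead_field(p, seed = s))
  pd <- do.call(small_params, c(sym, viability_fraction = 0))
  dead <- lapply(c(150, 600), function(e)
    generate_bead_field(pd, seed = 5, exposure_ms = c(pi = e)))
  cfg <- suppressWarnings(match_pi_setup(dead, live, c(150, 600)))
  expect_equal(cfg$exposure_pi_ms, cfg$exposure_fda_ms)
  expect_lt(abs(cfg$low_pi - cfg$low_fda), 3)
})

test_that("calibration failure reports the best achievable mismatch", {
  live <- lapply(1:2, function(s)
    generate_bead_field(small_params(per_cell_intensity = c(fda = 4.8, pi = 0.72)),
                        seed = s))
  pd <- small_params(viability_fraction = 0)
  dead <- list(generate_bead_field(pd, seed = 5, exposure_ms = c(pi = 600)))
  err <- tryCatch(suppressWarnings(match_pi_setup(dead, live, 600)),
                  error = function(e) e)
  expect_s3_class(err, "bv_calibration_error")
  expect_true(is.finite(err$data$mismatch))
  expect_gt(err$data$mismatch, 0.05)
})

test_that("overspill is zero without crosstalk and recovers an injected 10% leak", {
  # no crosstalk, no noise: exactly zero in both directions
  p0 <- tiny_params(noise_sd = 0)
  live0 <- generate_bead_field(p0, seed = 2)
  rep0 <- suppressWarnings(check_overspill(list(live0)))
  expect_identical(rep0$fda_into_pi, 0)
  expect_true(rep0$pass)

  # injected 10% FDA->PI leak is recovered (threshold clips some dim spill)
  px <- small_params(crosstalk_fda_to_pi = 0.10)
  livex <- lapply(1:3, function(s) generate_bead_field(px, seed = s))
  repx <- suppressWarnings(check_overspill(livex))
  expect_gt(repx$fda_into_pi, 0.05)
  expect_lt(repx$fda_into_pi, 0.13)
  expect_false(repx$pass)

  # a background-only field reports 0/0 as zero and passes
  pe <- tiny_params(cells_per_ml_beads = 1)
  empty <- generate_bead_field(pe, seed = 4)
  repe <- suppressWarnings(check_overspill(list(empty), low_fda = 41, low_pi = 41))
  expect_identical(repe$fda_into_pi, 0)
  expect_identical(repe$pi_into_fda, 0)
  expect_true(repe$pass)

  # mixed fields are rejected
  pm <- tiny_params(viability_fraction = 0.5)
  expect_param_error(check_overspill(list(generate_bead_field(pm, seed = 1))))
})
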