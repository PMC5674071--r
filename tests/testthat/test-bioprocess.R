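test_that("nutrient bounds are strict: above 15 mM glucose, below 10 mM lactate", {
  log <- data.frame(time_h = 1:4,
                    glucose_mM = c(16, 14, 15, 20),
                    lactate_mM = c(9, 9, 9, 10))
  v <- check_nutrient_bounds(log)
  expect_equal(nrow(v[v$variable == "glucose_mM", ]), 2)  # 14 and exactly 15
  expect_equal(v$time_h[v$variable == "lactate_mM"], 4)   # exactly 10 violates
  clean <- check_nutrient_bounds(data.frame(time_h = 1, glucose_mM = 16,
                                            lactate_mM = 9))
  expect_equal(nrow(clean), 0)
  expect_param_error(check_nutrient_bounds(log[0, ]))
})

test_that("oxygen consumption matches the dimensional-analysis oracle and is bilinear", {
  # 10 uM drop, 380 mL/min, 8e10 cells:
  # 10 umol/L * 0.38 L/min / 60 / 8e10 * 1e9 fmol/umol
  expect_equal(oxygen_consumption_per_cell(26, 21, 380, 8e10, sat_uM = 200),
               10 * 0.38 / 60 / 8e10 * 1e9)
  expect_equal(oxygen_consumption_per_cell(30, 30, 100, 1e10), 0)

  set.seed(44)
  for (i in 1:100) {
    di <- runif(1, 10, 90); dout <- runif(1, 0, di)
    fl <- runif(1, 10, 1000); n <- runif(1, 1e8, 1e12); sat <- runif(1, 150, 250)
    base <- oxygen_consumption_per_cell(di, dout, fl, n, sat)
    oracle <- ((di - dout) / 100 * sat) * (fl / 1000 / 60) / n * 1e9
    expect_equal(base, oracle, tolerance = 1e-12)
    expect_equal(oxygen_consumption_per_cell(di, dout, 2 * fl, n, sat), 2 * base)
    expect_equal(oxygen_consumption_per_cell(di, dout, fl, 2 * n, sat), base / 2)
    mid <- (di + dout) / 2
    expect_equal(oxygen_consumption_per_cell(mid, dout, fl, n, sat), base / 2,
                 tolerance = 1e-9)
  }
  expect_warning(oxygen_consumption_per_cell(20, 25, 100, 1e10), "negative")
  expect_param_error(oxygen_consumption_per_cell(26, 21, 380, 0))
})

test_that("production efficiency reproduces the harvest-density worked example", {
  pe <- production_efficiency(2.59e7, 3.27e7)
  expect_equal(pe$percent, 26L)
  expect_equal(production_efficiency(5, 5)$percent, 0L)
  expect_equal(production_efficiency(1e7, 2e7)$percent, 100L)
  expect_param_error(production_efficiency(0, 1e7))
})

test_that("viability drops summarise to the documented mean and SEM", {
  s <- viability_drop_summary(rbind(c(91.3, 87.2), c(96.8, 86.6), c(96.3, 92.0)))
  expect_equal(s$mean_drop, 6.2, tolerance = 1e-9)
  expect_equal(round(s$sem, 1), 2.0)
  expect_equal(s$n, 3)

  one <- viability_drop_summary(rbind(c(95, 95)))
  expect_equal(one$mean_drop, 0)
  expect_true(is.na(one$sem))

  # translation invariance of the mean drop
  set.seed(9)
  for (i in 1:25) {
    st <- runif(3, 20, 80); en <- st - runif(3, 0, 10); c0 <- runif(1, -10, 10)
    expect_equal(viability_drop_summary(cbind(st + c0, en + c0))$mean_drop,
                 viability_drop_summary(cbind(st, en))$mean_drop,
                 tolerance = 1e-9)
  }
  expect_param_error(viability_drop_summary(matrix(numeric(0), ncol = 2)))
  expect_param_error(viability_drop_summary(rbind(c(120, 90))))
})

test_that("bilirubin functional value converts a linear rise to mg per 1e11 cells per day", {
  ser <- data.frame(time_h = 0:8, conc = seq(0, 10, length.out = 9),
                    volume_L = 8)
  fv <- functional_value_bilirubin(ser, cell_count = 7e10)
  # 1.25 uM/h * 8 L * 584.66 ug/umol -> mg/h; x24; x(1e11/7e10)
  expect_equal(fv$mg_per_1e11_cells_per_day,
               1.25 * 8 * 584.66 / 1000 * 24 * 1e11 / 7e10, tolerance = 1e-9)
  expect_lt(abs(fv$mg_per_1e11_cells_per_day - 200.4), 0.1)

  flat <- functional_value_bilirubin(
    data.frame(time_h = 0:8, conc = 5, volume_L = 8), cell_count = 7e10)
  expect_equal(flat$mg_per_1e11_cells_per_day, 0, tolerance = 1e-12)

  # the analysis window excludes the early dilution artefact
  dil <- ser
  dil$conc[1] <- 40   # dilution spike at t = 0 would corrupt the slope
  fv2 <- functional_value_bilirubin(dil, cell_count = 7e10)
  expect_equal(fv2$mg_per_1e11_cells_per_day, fv$mg_per_1e11_cells_per_day,
               tolerance = 1e-9)

  expect_param_error(functional_value_bilirubin(ser[1:2, ], cell_count = 7e10))
  expect_param_error(functional_value_bilirubin(ser, cell_count = 0))
  ref <- bilirubin_reference()
  expect_equal(ref$physiological_mg_per_1e11_cells_per_day, 5)
  expect_equal(ref$observed_mg_per_1e11_cells_per_day, 88.2)
})

test_that("secretion rate normalises per million cells per hour", {
  ser <- data.frame(time_h = 0:10, conc = seq(0, 100, length.out = 11),
                    volume_L = 1)
  sr <- secretion_rate(ser, cell_count = 1e9)
  expect_equal(sr$ng_per_1e6_cells_per_h, 10, tolerance = 1e-9)
  expect_equal(sr$ng_per_1e6_cells_per_day, 240, tolerance = 1e-9)
  expect_equal(secretion_rate(ser, cell_count = 5e8)$ng_per_1e6_cells_per_h,
               20, tolerance = 1e-9)  # halving cells doubles the per-cell rate
  flat <- secretion_rate(data.frame(time_h = 0:4, conc = 7, volume_L = 1), 1e9)
  expect_equal(flat$ng_per_1e6_cells_per_h, 0, tolerance = 1e-12)
})

test_that("protein AUC matches closed forms and an independent integrator", {
  expect_equal(protein_auc_mg(data.frame(time_h = 0:5, conc = 0, volume_L = 4)), 0)

  # triangle: 0 -> 1000 ng/mL over 6 h in 2 L = 1/2 * 6 h * 2 mg
  tri <- data.frame(time_h = c(0, 6), conc = c(0, 1000), volume_L = 2)
  expect_equal(protein_auc_mg(tri), 0.5 * 6 * 2, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    ser <- data.frame(time_h = sort(runif(n, 0, 24)),
                      conc = runif(n, 0, 500), volume_L = runif(1, 1, 10))
    m <- ser$conc * ser$volume_L / 1000
    expect_equal(protein_auc_mg(ser), pracma::trapz(ser$time_h, m),
                 tolerance = 1e-9)
  }

  # additivity over concatenated windows
  ser <- data.frame(time_h = 0:10, conc = runif(11, 0, 100), volume_L = 3)
  expect_equal(protein_auc_mg(ser),
               protein_auc_mg(ser[1:6, ]) + protein_auc_mg(ser[6:11, ]),
               tolerance = 1e-12)
  expect_param_error(protein_auc_mg(ser[1, ]))
})

test_that("the DO setpoint escalates once, never de-escalates, and is absorbing", {
  cfgdo <- list(low_trigger = 10, setpoints = c(21, 35))
  expect_equal(do_setpoint_recipe(15, 21, cfgdo), 21)
  expect_equal(do_setpoint_recipe(9.9, 21, cfgdo), 35)
  expect_equal(do_setpoint_recipe(80, 35, cfgdo), 35)
  expect_equal(do_setpoint_recipe(1, 35, cfgdo), 35)
  expect_param_error(do_setpoint_recipe(10, 28, cfgdo))
  expect_param_error(do_setpoint_recipe(10, 21, list(setpoints = c(21, 35))))

  set.seed(3)
  for (i in 1:20) {
    readings <- runif(30, 0, 40)
    traj <- Reduce(function(sp, r) do_setpoint_recipe(r, sp, cfgdo),
                   readings, accumulate = TRUE, init = 21)
    expect_true(all(diff(traj) >= 0))
  }
})

test_that("media:biomass ratio reproduces the 1:46 process figure", {
  r <- media_biomass_ratio(2.5, 116)
  expect_equal(r$ratio, "1:46")
  expect_equal(r$n, 46.4)
  expect_equal(media_biomass_ratio(1, 1)$ratio, "1:1")
  expect_equal(media_biomass_ratio(2, 92.8)$n, 46.4)
  expect_param_error(media_biomass_ratio(0, 116))
})

test_that("media regimes are valid schedules with the day-4 change as default", {
  r <- media_regime()
  expect_equal(r$day, c(4, 7, 9, 11))
  expect_true(all(diff(r$day) > 0))
  expect_true(all(r$percent_replaced > 0 & r$percent_replaced <= 100))
  r5 <- media_regime("day5")
  expect_equal(r5$day[1], 5)
})
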