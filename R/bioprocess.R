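# Bioreactor-side quantifications: nutrient safety bounds, oxygen mass
# balance, production efficiency, viability-drop summaries, functional-value
# and secretion-rate normalisations, protein AUC, media:biomass ratio and
# the dissolved-oxygen setpoint escalation rule.

#' Flag nutrient excursions beyond the safe culture bounds
#'
#' The process keeps glucose strictly above 15 mM (cell nutrition) and
#' lactate strictly below 10 mM (hydrogel stability, growth toxicity).
#' Bounds are strict as stated, so a sample sitting exactly on a bound is a
#' violation.
#'
#' @param log A process log (see [read_process_log()]) or any data frame
#'   with `time_h`, `glucose_mM` and `lactate_mM` columns.
#' @param glucose_min_mM,lactate_max_mM The bounds (defaults as validated).
#' @return Data frame of violations: `time_h`, `variable`, `value`,
#'   `bound`. Zero rows when the run stayed within bounds.
#' @export
check_nutrient_bounds <- function(log, glucose_min_mM = 15,
                                  lactate_max_mM = 10) {
  if (!is.data.frame(log) ||
      !all(c("time_h", "glucose_mM", "lactate_mM") %in% names(log)))
    stop_input("log must contain time_h, glucose_mM and lactate_mM")
  if (!nrow(log)) stop_param("log must be non-empty")
  g <- which(log$glucose_mM <= glucose_min_mM)
  l <- which(log$lactate_mM >= lactate_max_mM)
  rbind(
    data.frame(time_h = log$time_h[g],
               variable = rep("glucose_mM", length(g)),
               value = log$glucose_mM[g],
               bound = rep(glucose_min_mM, length(g))),
    data.frame(time_h = log$time_h[l],
               variable = rep("lactate_mM", length(l)),
               value = log$lactate_mM[l],
               bound = rep(lactate_max_mM, length(l)))
  )
}

#' Per-cell oxygen consumption from a flow mass balance
#'
#' Converts the dissolved-oxygen drop across the bead chamber into a
#' per-cell consumption rate:
#' `((do_in - do_out)/100 * sat_uM)` umol/L times the flow in L/s, divided
#' by the cell count, expressed in fmol/cell/s. The saturation
#' concentration at 100% DO is an explicit argument (default 200 uM,
#' air-saturated culture medium at 37 C) because probe calibrations differ.
#' A negative result (outlet above inlet) is returned but flagged with a
#' warning, as it usually indicates probe drift or direct oxygenation
#' between the probes.
#'
#' @param do_in_pct,do_out_pct Dissolved oxygen, percent of saturation,
#'   before and after the chamber.
#' @param flow_mL_min Perfusion flow in mL/min (>= 0).
#' @param cell_count Total viable cells (> 0).
#' @param sat_uM Oxygen concentration at 100% saturation, umol/L.
#' @return Consumption in fmol/cell/second (vectorised over the DO/flow
#'   arguments).
#' @examples
#' # 10 uM drop at 380 mL/min over 8e10 cells -> 7.92e-4 fmol/cell/s
#' oxygen_consumption_per_cell(26, 21, 380, 8e10, sat_uM = 200)
#' @export
oxygen_consumption_per_cell <- function(do_in_pct, do_out_pct, flow_mL_min,
                                        cell_count, sat_uM = 200) {
  if (any(!is.finite(cell_count)) || any(cell_count <= 0))
    stop_param("cell_count must be positive")
  if (any(flow_mL_min < 0)) stop_param("flow_mL_min must be >= 0")
  if (any(sat_uM <= 0)) stop_param("sat_uM must be positive")
  dc_uM <- (do_in_pct - do_out_pct) / 100 * sat_uM
  out <- dc_uM * (flow_mL_min / 1000 / 60) / cell_count * 1e9
  if (any(out < 0))
    warning("negative oxygen consumption (DO out exceeds DO in); value reported as-is",
            call. = FALSE)
  out
}

#' Production-efficiency improvement between two harvest densities
#'
#' @param density_old,density_new Harvest cell densities (cells/mL of
#'   biomass); `density_old` must be positive.
#' @return List with `percent` (rounded to the nearest integer, the
#'   reported figure) and `percent_unrounded`.
#' @examples
#' production_efficiency(2.59e7, 3.27e7)$percent  # 26
#' @export
production_efficiency <- function(density_old, density_new) {
  if (!is_scalar_number(density_old) || density_old <= 0)
    stop_param("density_old must be positive")
  if (!is_scalar_number(density_new) || density_new < 0)
    stop_param("density_new must be non-negative")
  u <- 100 * (density_new - density_old) / density_old
  list(percent = as.integer(round_half_up(u)), percent_unrounded = u)
}

#' Summarise viability drops over paired start/end measurements
#'
#' @param pairs Two-column matrix/data frame (start, end, both in percent)
#'   or a list of length-2 vectors.
#' @return List with `mean_drop`, `sem` (standard error of the mean; `NA`
#'   flagged for n = 1), `n` and the individual `drops`.
#' @examples
#' viability_drop_summary(rbind(c(91.3, 87.2), c(96.8, 86.6), c(96.3, 92.0)))
#' @export
viability_drop_summary <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop_param("pairs must be non-empty")
  if (ncol(pairs) != 2) stop_param("pairs must have two columns (start, end)")
  if (any(pairs < 0 | pairs > 100)) stop_param("percentages must lie in [0, 100]")
  drops <- pairs[, 1] - pairs[, 2]
  n <- length(drops)
  sem <- if (n > 1) stats::sd(drops) / sqrt(n) else NA_real_
  out <- list(mean_drop = mean(drops), sem = sem, n = n, drops = as.numeric(drops))
  if (n == 1) attr(out, "sem_undefined") <- TRUE
  out
}

#' Functional value of bilirubin conjugation, normalised to whole-liver scale
#'
#' Converts a conjugated-bilirubin concentration time series measured in the
#' treated plasma compartment into mg conjugated per 10^11 cells per day
#' (10^11 cells being the adult-liver reference against which roughly 5 mg
#' urinary conjugated bilirubin per day is excreted). The production rate is
#' the ordinary-least-squares slope of concentration over the analysis
#' window; the window starts at 1 h by default, excluding the initial
#' dilution artefact when plasma mixes with fluid held in the hydrogel.
#'
#' @param series Concentration series (see [read_concentration_series()]):
#'   data frame with `time_h`, `conc` (umol/L conjugated bilirubin) and
#'   `volume_L`.
#' @param cell_count Total viable cells in the biomass (> 0).
#' @param mw_g_per_mol Molar mass of conjugated bilirubin used for the
#'   umol-to-mg conversion; default 584.66 (bilirubin).
#' @param window Analysis window `c(from_h, to_h)`, inclusive.
#' @return List with `mg_per_1e11_cells_per_day`, the fitted
#'   `slope_uM_per_h`, and the `reference` constants (the 5 mg/day
#'   physiological figure and the 88.2 observed figure are documented
#'   context, not recomputed values).
#' @export
functional_value_bilirubin <- function(series, cell_count,
                                       mw_g_per_mol = 584.66,
                                       window = c(1, Inf)) {
  r <- fit_rate(series, window)
  if (!is_scalar_number(cell_count) || cell_count <= 0)
    stop_param("cell_count must be positive")
  mg_per_h <- r$slope * r$volume_L * mw_g_per_mol / 1000   # uM/h * L * ug/umol -> mg/h
  list(mg_per_1e11_cells_per_day = mg_per_h * 24 * 1e11 / cell_count,
       slope_uM_per_h = r$slope,
       volume_L = r$volume_L,
       reference = bilirubin_reference())
}

#' Reference constants for bilirubin conjugation
#'
#' Documented context for [functional_value_bilirubin()]: an adult excretes
#' about 5 mg conjugated bilirubin per day in urine (taking 10^11 total
#' liver cells), and the validated biomass achieved 88.2 mg conjugated per
#' 10^11 cells per day in liver-failure plasma. These are reference values,
#' not quantities the package recomputes.
#'
#' @return Named list with `physiological_mg_per_1e11_cells_per_day` and
#'   `observed_mg_per_1e11_cells_per_day`.
#' @export
bilirubin_reference <- function() {
  list(physiological_mg_per_1e11_cells_per_day = 5,
       observed_mg_per_1e11_cells_per_day = 88.2)
}

#' Protein secretion rate per million cells
#'
#' OLS slope of the protein concentration over the analysis window, scaled
#' by compartment volume and normalised per 10^6 cells. Reported per hour
#' and per day.
#'
#' @param series Data frame with `time_h`, `conc` (ng/mL) and `volume_L`.
#' @param cell_count Total viable cells (> 0).
#' @param window Analysis window in hours, inclusive; defaults to 1 h
#'   onward (see [functional_value_bilirubin()] for why).
#' @return List with `ng_per_1e6_cells_per_h`, `ng_per_1e6_cells_per_day`
#'   and the fitted `slope_ng_ml_per_h`.
#' @export
secretion_rate <- function(series, cell_count, window = c(1, Inf)) {
  r <- fit_rate(series, window)
  if (!is_scalar_number(cell_count) || cell_count <= 0)
    stop_param("cell_count must be positive")
  ng_per_h <- r$slope * r$volume_L * 1000     # ng/mL/h * mL -> ng/h
  per_1e6_h <- ng_per_h / (cell_count / 1e6)
  list(ng_per_1e6_cells_per_h = per_1e6_h,
       ng_per_1e6_cells_per_day = per_1e6_h * 24,
       slope_ng_ml_per_h = r$slope)
}

# OLS slope of conc over time within the window; volume is averaged over the
# window (it is constant in practice).
fit_rate <- function(series, window) {
  if (!is.data.frame(series) ||
      !all(c("time_h", "conc", "volume_L") %in% names(series)))
    stop_input("series must contain time_h, conc and volume_L")
  s <- series[series$time_h >= window[1] & series$time_h <= window[2], ]
  if (nrow(s) < 2)
    stop_param("at least two time points are required in the analysis window")
  fit <- stats::lm(conc ~ time_h, data = s)
  list(slope = unname(stats::coef(fit)[2]), volume_L = mean(s$volume_L))
}

#' Total protein mass area-under-curve
#'
#' Trapezoidal integral of the compartment protein mass (concentration
#' times volume, in mg) over time. Units are mg x h; following the
#' convention of the source quantifications the result is reported as the
#' "total mg produced over treatment".
#'
#' @param series Data frame with `time_h`, `conc` and `volume_L`.
#' @param conc_unit Unit of `conc`: `"ng_per_ml"` (default), `"ug_per_ml"`
#'   or `"mg_per_l"`.
#' @return Total mass AUC (scalar).
#' @export
protein_auc_mg <- function(series,
                           conc_unit = c("ng_per_ml", "ug_per_ml", "mg_per_l")) {
  conc_unit <- match.arg(conc_unit)
  if (!is.data.frame(series) ||
      !all(c("time_h", "conc", "volume_L") %in% names(series)))
    stop_input("series must contain time_h, conc and volume_L")
  if (nrow(series) < 2) stop_param("at least two time points are required")
  if (is.unsorted(series$time_h, strictly = TRUE))
    stop_input("time_h must be strictly increasing")
  fac <- switch(conc_unit, ng_per_ml = 1e-3, ug_per_ml = 1, mg_per_l = 1)
  m <- series$conc * series$volume_L * fac          # mg in the compartment
  t <- series$time_h
  sum(diff(t) * (m[-1] + m[-length(m)]) / 2)
}

#' Dissolved-oxygen setpoint escalation rule
#'
#' The supply vessel's DO setpoint starts at the lowest allowed value and
#' escalates automatically (21% to 35% on the validated process) when the
#' post-chamber DO reading falls below a trigger, ensuring the whole bead
#' bed stays oxygenated. The rule never de-escalates within a run and is
#' idempotent at the highest setpoint. The trigger level is
#' process-specific and therefore has no default.
#'
#' @param do_post_pct Post-chamber DO reading, percent saturation.
#' @param current_setpoint Current setpoint; must be one of
#'   `config$setpoints`.
#' @param config List with `low_trigger` (percent; required) and
#'   `setpoints` (ascending allowed setpoints, default `c(21, 35)`).
#' @return The new setpoint.
#' @export
do_setpoint_recipe <- function(do_post_pct, current_setpoint, config) {
  if (is.null(config$low_trigger) || !is_scalar_number(config$low_trigger))
    stop_param("config$low_trigger is required (no process-independent default exists)")
  setpoints <- sort(if (is.null(config$setpoints)) c(21, 35) else config$setpoints)
  i <- match(current_setpoint, setpoints)
  if (is.na(i)) stop_param("current_setpoint must be one of the allowed setpoints")
  if (i == length(setpoints)) return(current_setpoint)
  if (do_post_pct < config$low_trigger) setpoints[i + 1L] else current_setpoint
}

#' Biomass-to-media ratio
#'
#' @param biomass_L Bead (biomass) volume in litres (> 0).
#' @param media_L Culture media volume in litres.
#' @return List with `ratio` (string `"1:N"`, N rounded to the nearest
#'   integer), `n` (unrounded) and `n_rounded`.
#' @examples
#' media_biomass_ratio(2.5, 116)$ratio  # "1:46"
#' @export
media_biomass_ratio <- function(biomass_L, media_L) {
  if (!is_scalar_number(biomass_L) || biomass_L <= 0)
    stop_param("biomass_L must be positive")
  if (!is_scalar_number(media_L) || media_L < 0)
    stop_param("media_L must be non-negative")
  n <- media_L / biomass_L
  nr <- as.integer(round_half_up(n))
  list(ratio = sprintf("1:%d", nr), n = n, n_rounded = nr)
}

#' Media-change regimes of the production process
#'
#' Returns the fraction of culture media replaced on each process day.
#' `"day4"` is the shipped default (replacement moved to day 4, the regime
#' that improved production efficiency): days 4, 7, 9 and 11 at 50, 55
#' (reported as a 50-60% range; the midpoint is encoded), 70 and 80%.
#' `"day5"` is the earlier variant with a 25% replenishment on day 5.
#'
#' @param regime `"day4"` (default) or `"day5"`.
#' @return Data frame with `day` and `percent_replaced`.
#' @export
media_regime <- function(regime = c("day4", "day5")) {
  regime <- match.arg(regime)
  out <- switch(regime,
    day4 = data.frame(day = c(4, 7, 9, 11),
                      percent_replaced = c(50, 55, 70, 80)),
    day5 = data.frame(day = c(5, 7, 11),
                      percent_replaced = c(25, 55, 80)))
  validate_media_regime(out)
  out
}

validate_media_regime <- function(df) {
  if (!all(c("day", "percent_replaced") %in% names(df)))
    stop_input("a media regime needs day and percent_replaced columns")
  if (is.unsorted(df$day, strictly = TRUE))
    stop_param("media-change days must be increasing")
  if (any(df$percent_replaced <= 0 | df$percent_replaced > 100))
    stop_param("percent_replaced must lie in (0, 100]")
  invisible(df)
}
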