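#' Render an analysis report (JSON + human-readable text)
#'
#' Assembles viability results, calibration provenance and metrics tables
#' into one deterministic report: the same inputs always serialise to
#' byte-identical JSON. Every numeric entry carries its units, every
#' warning carries the rule that triggered it, and the calibration is
#' fingerprinted with a content hash so downstream consumers can tell which
#' configuration produced a number.
#'
#' @param results Named list; recognised entries are `viability` (a
#'   [quantify()] result), `metrics` (a named list of metric outputs) and
#'   `seed`. Empty results produce a valid report with zero sections.
#' @param config Optional [calibration_config()] recorded as provenance.
#' @return Object of class `bv_report`: list with `json` (one string),
#'   `text` (character vector of lines) and `data` (the report structure).
#' @export
render_report <- function(results = list(), config = NULL) {
  if (!is.list(results)) stop_param("results must be a list")
  rep <- list(tool = "beadviability",
              version = as.character(utils::packageVersion("beadviability")))
  if (!is.null(results$seed)) rep$seed <- as.integer(results$seed)
  if (!is.null(config)) {
    if (!inherits(config, "calibration_config"))
      stop_param("config must be a calibration_config")
    cj <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
    rep$calibration <- c(unclass(config), list(hash = fnv1a_hex(cj)))
  }
  sections <- character()
  if (!is.null(results$viability)) {
    v <- results$viability
    if (!inherits(v, "viability_result"))
      stop_param("results$viability must come from quantify()")
    rep$viability <- list(
      percent = if (v$undefined) NULL else v$percent,
      undefined = v$undefined,
      units = "percent",
      s_fda = v$s_fda, s_pi = v$s_pi,
      n_fields = v$n_fields,
      n_beads = if (is.na(v$n_beads)) NULL else v$n_beads,
      per_field_percent = v$per_field$percent,
      warnings = if (length(v$warnings))
        lapply(names(v$warnings), function(r)
          list(rule = r, message = unname(v$warnings[[r]])))
      else list()
    )
    sections <- c(sections, "viability")
  }
  if (!is.null(results$metrics)) {
    rep$metrics <- results$metrics
    sections <- c(sections, "metrics")
  }
  rep$sections <- as.list(sections)
  json <- as.character(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                        null = "null"))
  text <- c(sprintf("beadviability report (v%s)", rep$version))
  if (!is.null(rep$seed)) text <- c(text, sprintf("seed: %d", rep$seed))
  if (!is.null(rep$calibration))
    text <- c(text, sprintf(
      "calibration: FDA low %d @ %g ms | PI low %d @ %g ms | hash %s",
      rep$calibration$low_fda, rep$calibration$exposure_fda_ms,
      rep$calibration$low_pi, rep$calibration$exposure_pi_ms,
      rep$calibration$hash))
  if (!is.null(rep$viability)) {
    text <- c(text, if (rep$viability$undefined)
      "viability: undefined (no signal)"
      else sprintf("viability: %.2f %% (%d field(s))",
                   rep$viability$percent, rep$viability$n_fields))
    for (w in rep$viability$warnings)
      text <- c(text, sprintf("warning [%s]: %s", w$rule, w$message))
  }
  if (!is.null(rep$metrics))
    text <- c(text, sprintf("metrics: %s",
                            paste(names(rep$metrics), collapse = ", ")))
  if (!length(sections)) text <- c(text, "(no result sections)")
  structure(list(json = json, text = text, data = rep), class = "bv_report")
}

#' @export
print.bv_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
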