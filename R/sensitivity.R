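#' Define a one-way sensitivity scenario
#'
#' A scenario is a named list of transforms applied to a
#' [model_parameters()] object. Each transform addresses a parameter by its
#' dot-separated path (e.g. `"utilities.flexible_dosing_utility"`,
#' `"rate_ratios.nocturnal.value"`, `"event_costs.per_event"`) and either
#' replaces the value (`list(set = x)`, or a bare value) or multiplies it
#' (`list(multiply = k)`, which also works on whole named vectors such as
#' `event_costs.per_event`). A transform with `optional = TRUE` is skipped
#' when the path does not exist in the target (used for bolus fields, which
#' basal-oral parameter sets lack). The base case is the empty transform
#' list.
#'
#' @param name Scenario name.
#' @param transforms Named list of transforms (names are parameter paths).
#' @param groups Optional character vector restricting the scenario to some
#'   patient groups (`NULL`: applies to all).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, transforms = list(), groups = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(transforms))
  if (length(transforms) && is.null(names(transforms)))
    stop("transforms must be named by parameter path", call. = FALSE)
  structure(list(name = name, transforms = transforms, groups = groups),
            class = "scenario_spec")
}

#' Apply a scenario to a parameter set
#'
#' Returns a modified, revalidated copy; the input is untouched. An unknown
#' parameter path is an error unless the transform is marked optional.
#'
#' @param params A [model_parameters()] object.
#' @param spec A [scenario_spec()].
#' @return A new `model_parameters` object.
#' @export
apply_scenario <- function(params, spec) {
  if (!is.null(spec$groups) && !params$group %in% spec$groups)
    return(params)
  out <- params
  for (path in names(spec$transforms)) {
    tr <- spec$transforms[[path]]
    if (!is.list(tr)) tr <- list(set = tr)
    current <- get_param(out, path)
    if (is.null(current)) {
      if (isTRUE(tr$optional)) next
      stop(sprintf("unknown parameter path `%s`", path), call. = FALSE)
    }
    value <- if (!is.null(tr$multiply)) current * tr$multiply else tr$set
    if (is.null(value))
      stop(sprintf("transform for `%s` has neither `set` nor `multiply`", path),
           call. = FALSE)
    out <- set_param(out, path, value)
  }
  validate_model_parameters(out)
}

#' The published one-way sensitivity scenario set
#'
#' The scenarios varied in the source analysis: a 5-year horizon (no
#' discounting, so the ICER is unchanged), zero mortality after severe
#' hypoglycaemia, hypoglycaemia management costs +/-10%, no difference in
#' insulin dose between treatments, no difference in hypoglycaemia event
#' rates (all rate ratios set to 1, leaving the insulin-cost increment and
#' the flexible-dosing utility as the only differences), an alternative
#' flexible-dosing utility of 0.013, the flexible-dosing benefit restricted
#' to 50% of patients, and no flexible-dosing benefit. Alternative
#' published event-rate sets are study-specific inputs not reproduced here;
#' supply them as additional [scenario_spec()]s replacing
#' `glargine_rates.*` and `rate_ratios.*` paths.
#'
#' @return Named list of [scenario_spec()]s, including the base case.
#' @export
table4_scenarios <- function() {
  specs <- list(
    scenario_spec("base_case"),
    scenario_spec("time_horizon_5_years",
                  list(horizon_years = 5)),
    scenario_spec("zero_mortality_after_severe",
                  list(utilities.mortality_risk_severe = 0)),
    scenario_spec("event_costs_plus_10pct",
                  list(event_costs.per_event = list(multiply = 1.10))),
    scenario_spec("event_costs_minus_10pct",
                  list(event_costs.per_event = list(multiply = 0.90))),
    scenario_spec("no_dose_difference",
                  list(regimen.basal_dose_ratio = 1,
                       regimen.basal_ratio_significant = TRUE,
                       regimen.bolus_dose_ratio = list(set = 1, optional = TRUE),
                       regimen.bolus_ratio_significant =
                         list(set = TRUE, optional = TRUE))),
    scenario_spec("no_hypoglycaemia_difference",
                  list(rate_ratios.daytime.value = 1,
                       rate_ratios.daytime.significant = TRUE,
                       rate_ratios.nocturnal.value = 1,
                       rate_ratios.nocturnal.significant = TRUE,
                       rate_ratios.severe.value = 1,
                       rate_ratios.severe.significant = TRUE)),
    scenario_spec("flexible_dosing_utility_0.013",
                  list(utilities.flexible_dosing_utility = 0.013)),
    scenario_spec("flexible_dosing_50pct_of_patients",
                  list(utilities.fraction_benefiting_flexible = 0.5)),
    scenario_spec("no_flexible_dosing_utility",
                  list(utilities.flexible_dosing_utility = 0)))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Run a set of one-way scenarios
#'
#' Evaluates the model under each scenario and tabulates the incremental
#' results. Deterministic: the same specs always produce the same table.
#'
#' @param params Base-case [model_parameters()].
#' @param specs List of [scenario_spec()]s (default [table4_scenarios()]).
#' @return Data frame with one row per scenario: `scenario`, `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` when undefined) and `dominance`.
#' @export
run_scenarios <- function(params, specs = table4_scenarios()) {
  if (!any(vapply(specs, function(s) length(s$transforms) == 0L, logical(1))))
    specs <- c(list(scenario_spec("base_case")), specs)
  rows <- lapply(specs, function(spec) {
    cmp <- evaluate_group(apply_scenario(params, spec))$comparison
    data.frame(scenario = spec$name, delta_cost = cmp$delta_cost,
               delta_qalys = cmp$delta_qalys, icer = cmp$icer,
               dominance = cmp$dominance, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Tornado-style one-way parameter sweeps
#'
#' Sets each parameter to its low and high value in turn, recomputes the
#' incremental result, and orders parameters by the width of the induced
#' ICER interval. For sweeps that cross into dominance the cost/QALY ratio
#' is still reported (it is then negative) so that bar widths stay
#' comparable; the dominance class at each end is tabulated alongside.
#'
#' @param params Base-case [model_parameters()].
#' @param sweeps Data frame with columns `parameter` (path), `low`, `high`.
#' @return Data frame sorted by decreasing `width`: `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `width`, `dominance_low`,
#'   `dominance_high`.
#' @export
tornado <- function(params, sweeps) {
  stopifnot(all(c("parameter", "low", "high") %in% names(sweeps)),
            all(sweeps$low <= sweeps$high))
  ratio_at <- function(path, value) {
    spec <- scenario_spec("sweep", stats::setNames(list(value), path))
    cmp <- evaluate_group(apply_scenario(params, spec))$comparison
    list(ratio = if (cmp$delta_qalys != 0)
           cmp$delta_cost / cmp$delta_qalys else NA_real_,
         dominance = cmp$dominance)
  }
  rows <- lapply(seq_len(nrow(sweeps)), function(i) {
    lo <- ratio_at(sweeps$parameter[i], sweeps$low[i])
    hi <- ratio_at(sweeps$parameter[i], sweeps$high[i])
    data.frame(parameter = sweeps$parameter[i],
               low = sweeps$low[i], high = sweeps$high[i],
               icer_low = lo$ratio, icer_high = hi$ratio,
               width = abs(hi$ratio - lo$ratio),
               dominance_low = lo$dominance, dominance_high = hi$dominance,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

#' Default tornado sweep table for a parameter set
#'
#' Rate ratios and dose ratios are swept +/-20% and +/-10% around their
#' effective values, per-event costs +/-10%, and the flexible-dosing
#' utility +/-50%.
#'
#' @param params A [model_parameters()] object.
#' @return Data frame suitable for [tornado()].
#' @export
default_sweeps <- function(params) {
  eff <- effective_ratio(ratio_values(params$rate_ratios),
                         ratio_flags(params$rate_ratios))
  rows <- list()
  for (cat in hypo_categories()) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("rate_ratios.%s.value", cat),
      low = 0.8 * eff[[cat]], high = 1.2 * eff[[cat]])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("event_costs.per_event.%s", cat),
      low = 0.9 * params$event_costs$per_event[[cat]],
      high = 1.1 * params$event_costs$per_event[[cat]])
  }
  basal_eff <- effective_ratio(params$regimen$basal_dose_ratio,
                               params$regimen$basal_ratio_significant)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = "regimen.basal_dose_ratio",
    low = 0.9 * basal_eff, high = 1.1 * basal_eff)
  if (has_bolus(params$regimen)) {
    bolus_eff <- effective_ratio(params$regimen$bolus_dose_ratio,
                                 params$regimen$bolus_ratio_significant)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "regimen.bolus_dose_ratio",
      low = 0.9 * bolus_eff, high = 1.1 * bolus_eff)
  }
  flex <- params$utilities$flexible_dosing_utility
  if (flex > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "utilities.flexible_dosing_utility",
      low = 0.5 * flex, high = 1.5 * flex)
  do.call(rbind, rows)
}
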