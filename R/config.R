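#' Load model parameters from a YAML configuration
#'
#' Reads one patient-group configuration and returns a validated
#' [model_parameters()] object. Unknown keys are rejected (fail-fast) so a
#' misspelled field cannot silently fall back to a default. Defaults applied
#' when a key is absent: `prices.days_per_year = 365`, `horizon_years = 1`,
#' `discount_rate = 0`, and the optional utility fields documented in
#' [utility_inputs()].
#'
#' The schema (see the packaged configurations written by
#' [write_calibration()] for complete examples):
#' \preformatted{
#' group: T2DM_BOT
#' regimen:
#'   basal_dose_glargine: 28.11
#'   basal_dose_ratio: 0.90
#'   basal_ratio_significant: yes
#'   # bolus_dose_glargine / bolus_dose_ratio / bolus_ratio_significant:
#'   # required for basal-bolus groups, forbidden for T2DM_BOT
#' prices:
#'   price_basal_glargine: 0.055967
#'   price_basal_degludec: 0.086086
#'   # price_bolus required with a bolus component
#' glargine_rates: {daytime: 23.12, nocturnal: 13.38, severe: 0.10}
#' rate_ratios:
#'   daytime:   {value: 1.00, significant: no}
#'   nocturnal: {value: 0.64, significant: yes}
#'   severe:    {value: 0.14, significant: yes}
#' event_costs: {daytime: 0.65, nocturnal: 33.19, severe: 508.10}
#' utilities:
#'   baseline_utility: 0.9297
#'   disutility_daytime: 0.00415
#'   disutility_nocturnal: 0.00649
#'   disutility_severe: 0.0725
#' }
#'
#' @param source Path to a YAML file, or a YAML string.
#' @return A validated `model_parameters` object.
#' @export
load_parameters <- function(source) {
  cfg <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    yaml::read_yaml(source) else yaml::yaml.load(source)
  if (!is.list(cfg)) stop("configuration did not parse to a mapping", call. = FALSE)
  known_top <- c("group", "regimen", "prices", "glargine_rates", "rate_ratios",
                 "event_costs", "utilities", "horizon_years", "discount_rate")
  reject_unknown(cfg, known_top, "")
  for (key in c("group", "regimen", "prices", "glargine_rates", "rate_ratios",
                "event_costs", "utilities"))
    if (is.null(cfg[[key]])) stop_field(key, "missing")

  reject_unknown(cfg$regimen,
                 c("basal_dose_glargine", "basal_dose_ratio",
                   "basal_ratio_significant", "bolus_dose_glargine",
                   "bolus_dose_ratio", "bolus_ratio_significant"), "regimen")
  regimen <- do.call(insulin_regimen, cfg$regimen)

  reject_unknown(cfg$prices,
                 c("price_basal_glargine", "price_basal_degludec",
                   "price_bolus", "days_per_year"), "prices")
  prices <- do.call(unit_prices, cfg$prices)

  reject_unknown(cfg$glargine_rates, hypo_categories(), "glargine_rates")
  for (cat in hypo_categories())
    if (is.null(cfg$glargine_rates[[cat]]))
      stop_field(paste0("glargine_rates.", cat), "missing")
  rates <- do.call(hypo_rates, cfg$glargine_rates)

  reject_unknown(cfg$rate_ratios, hypo_categories(), "rate_ratios")
  rr <- list()
  for (cat in hypo_categories()) {
    node <- cfg$rate_ratios[[cat]]
    if (is.null(node)) stop_field(paste0("rate_ratios.", cat), "missing")
    reject_unknown(node, c("value", "significant"), paste0("rate_ratios.", cat))
    rr[[cat]] <- node$value
    rr[[paste0(cat, "_significant")]] <- node$significant
  }
  ratios <- do.call(hypo_rate_ratios, rr)

  reject_unknown(cfg$event_costs, c(hypo_categories(), "inflation_factor"),
                 "event_costs")
  for (cat in hypo_categories())
    if (is.null(cfg$event_costs[[cat]]))
      stop_field(paste0("event_costs.", cat), "missing")
  costs <- do.call(event_costs, cfg$event_costs)

  reject_unknown(cfg$utilities,
                 c("baseline_utility", "disutility_daytime",
                   "disutility_nocturnal", "disutility_severe",
                   "flexible_dosing_utility", "fraction_benefiting_flexible",
                   "mortality_risk_severe", "qaly_loss_per_death"), "utilities")
  utilities <- do.call(utility_inputs, cfg$utilities)

  model_parameters(group = cfg$group %||% stop_field("group", "missing"),
                   regimen = regimen, prices = prices, glargine_rates = rates,
                   rate_ratios = ratios, event_costs = costs,
                   utilities = utilities,
                   horizon_years = cfg$horizon_years %||% 1,
                   discount_rate = cfg$discount_rate %||% 0)
}

reject_unknown <- function(node, known, prefix) {
  if (!is.list(node))
    stop_field(if (nzchar(prefix)) prefix else "<root>", "must be a mapping")
  extra <- setdiff(names(node), known)
  if (length(extra))
    stop_field(paste0(if (nzchar(prefix)) paste0(prefix, ".") else "", extra[[1L]]),
               "unknown key")
  invisible(NULL)
}

#' Serialise model parameters to the YAML configuration dialect
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p` (numeric values are written with 15 significant digits).
#'
#' @param params A `model_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  cfg <- as_config_list(params)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

as_config_list <- function(params) {
  reg <- params$regimen
  regimen <- list(basal_dose_glargine = reg$basal_dose_glargine,
                  basal_dose_ratio = reg$basal_dose_ratio,
                  basal_ratio_significant = reg$basal_ratio_significant)
  if (has_bolus(reg)) {
    regimen$bolus_dose_glargine <- reg$bolus_dose_glargine
    regimen$bolus_dose_ratio <- reg$bolus_dose_ratio
    regimen$bolus_ratio_significant <- reg$bolus_ratio_significant
  }
  prices <- list(price_basal_glargine = params$prices$price_basal_glargine,
                 price_basal_degludec = params$prices$price_basal_degludec)
  if (!is.null(params$prices$price_bolus))
    prices$price_bolus <- params$prices$price_bolus
  prices$days_per_year <- params$prices$days_per_year
  ratios <- lapply(hypo_categories(), function(cat)
    list(value = params$rate_ratios[[cat]]$value,
         significant = params$rate_ratios[[cat]]$significant))
  names(ratios) <- hypo_categories()
  u <- params$utilities
  list(group = params$group,
       regimen = regimen,
       prices = prices,
       glargine_rates = as.list(unclass(params$glargine_rates)),
       rate_ratios = ratios,
       event_costs = c(as.list(params$event_costs$per_event),
                       list(inflation_factor = params$event_costs$inflation_factor)),
       utilities = list(baseline_utility = u$baseline_utility,
                        disutility_daytime = u$disutility[["daytime"]],
                        disutility_nocturnal = u$disutility[["nocturnal"]],
                        disutility_severe = u$disutility[["severe"]],
                        flexible_dosing_utility = u$flexible_dosing_utility,
                        fraction_benefiting_flexible = u$fraction_benefiting_flexible,
                        mortality_risk_severe = u$mortality_risk_severe,
                        qaly_loss_per_death = u$qaly_loss_per_death),
       horizon_years = params$horizon_years,
       discount_rate = params$discount_rate)
}
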