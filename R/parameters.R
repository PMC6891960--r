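#' Apply a rate ratio only when statistically significant
#'
#' Treatment-effect ratios (dose ratios and hypoglycaemia event-rate ratios)
#' taken from meta-analysis are applied in the model only when the underlying
#' estimate was statistically significant; a non-significant ratio is
#' replaced by 1, i.e. no treatment difference is assumed.
#'
#' @param ratio Numeric vector of positive ratios (degludec / glargine U100).
#' @param significant Logical vector; was the estimate significant?
#' @return Numeric vector: `ratio` where significant, 1 otherwise.
#' @examples
#' effective_ratio(0.83, TRUE)   # 0.83
#' effective_ratio(0.88, FALSE)  # 1
#' @export
effective_ratio <- function(ratio, significant) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("`ratio` must be positive and finite", call. = FALSE)
  ifelse(significant, ratio, 1)
}

#' Insulin regimen: observed glargine doses and degludec/glargine dose ratios
#'
#' Doses are daily insulin use observed under glargine U100; the degludec
#' doses are derived by multiplying by the (significance-gated) dose ratio.
#' Basal-oral therapy has no bolus component: leave the bolus arguments
#' `NULL`.
#'
#' @param basal_dose_glargine Basal dose under glargine U100, units/day.
#' @param basal_dose_ratio Degludec/glargine basal dose ratio.
#' @param basal_ratio_significant Logical; significance of the basal ratio.
#' @param bolus_dose_glargine,bolus_dose_ratio,bolus_ratio_significant
#'   Bolus analogues; all `NULL` for basal-oral therapy.
#' @return An object of class `insulin_regimen`.
#' @export
insulin_regimen <- function(basal_dose_glargine, basal_dose_ratio,
                            basal_ratio_significant,
                            bolus_dose_glargine = NULL,
                            bolus_dose_ratio = NULL,
                            bolus_ratio_significant = NULL) {
  check_number(basal_dose_glargine, "regimen.basal_dose_glargine", 0, strict_lower = TRUE)
  check_number(basal_dose_ratio, "regimen.basal_dose_ratio", 0, strict_lower = TRUE)
  check_flag(basal_ratio_significant, "regimen.basal_ratio_significant")
  has_bolus <- !is.null(bolus_dose_glargine)
  if (has_bolus) {
    check_number(bolus_dose_glargine, "regimen.bolus_dose_glargine", 0, strict_lower = TRUE)
    check_number(bolus_dose_ratio, "regimen.bolus_dose_ratio", 0, strict_lower = TRUE)
    check_flag(bolus_ratio_significant, "regimen.bolus_ratio_significant")
  } else if (!is.null(bolus_dose_ratio) || !is.null(bolus_ratio_significant)) {
    stop_field("regimen.bolus_dose_glargine",
               "bolus ratio given without a bolus dose")
  }
  structure(list(basal_dose_glargine = basal_dose_glargine,
                 basal_dose_ratio = basal_dose_ratio,
                 basal_ratio_significant = basal_ratio_significant,
                 bolus_dose_glargine = bolus_dose_glargine,
                 bolus_dose_ratio = bolus_dose_ratio,
                 bolus_ratio_significant = bolus_ratio_significant),
            class = "insulin_regimen")
}

has_bolus <- function(regimen) !is.null(regimen$bolus_dose_glargine)

#' Insulin unit prices
#'
#' Pharmacy selling prices (purchase price including VAT), BGN per insulin
#' unit. The bolus price is required only for regimens with a bolus
#' component.
#'
#' @param price_basal_glargine,price_basal_degludec Basal prices, BGN/unit.
#' @param price_bolus Bolus insulin price, BGN/unit, or `NULL`.
#' @param days_per_year Days of treatment per year (default 365).
#' @return An object of class `unit_prices`.
#' @export
unit_prices <- function(price_basal_glargine, price_basal_degludec,
                        price_bolus = NULL, days_per_year = 365) {
  check_number(price_basal_glargine, "prices.price_basal_glargine", 0, strict_lower = TRUE)
  check_number(price_basal_degludec, "prices.price_basal_degludec", 0, strict_lower = TRUE)
  if (!is.null(price_bolus))
    check_number(price_bolus, "prices.price_bolus", 0, strict_lower = TRUE)
  check_number(days_per_year, "prices.days_per_year", 360, 366)
  structure(list(price_basal_glargine = price_basal_glargine,
                 price_basal_degludec = price_basal_degludec,
                 price_bolus = price_bolus,
                 days_per_year = days_per_year),
            class = "unit_prices")
}

#' Annual hypoglycaemia event rates
#'
#' Events per patient per year in the three categories (non-severe daytime,
#' non-severe nocturnal, severe).
#'
#' @param daytime,nocturnal,severe Non-negative rates, events/patient/year.
#' @return Named numeric vector of class `hypo_rates`.
#' @export
hypo_rates <- function(daytime, nocturnal, severe) {
  check_number(daytime, "rates.daytime", 0)
  check_number(nocturnal, "rates.nocturnal", 0)
  check_number(severe, "rates.severe", 0)
  structure(c(daytime = unname(daytime), nocturnal = unname(nocturnal),
              severe = unname(severe)),
            class = "hypo_rates")
}

#' Degludec/glargine hypoglycaemia rate ratios with significance gating
#'
#' One ratio per event category with a significance flag; a non-significant
#' ratio is applied as 1 (see [effective_ratio()]).
#'
#' @param daytime,nocturnal,severe Positive rate ratios.
#' @param daytime_significant,nocturnal_significant,severe_significant
#'   Logical significance flags.
#' @return An object of class `hypo_rate_ratios` with elements per category,
#'   each a list with `value` and `significant`.
#' @export
hypo_rate_ratios <- function(daytime = 1, nocturnal = 1, severe = 1,
                             daytime_significant = FALSE,
                             nocturnal_significant = FALSE,
                             severe_significant = FALSE) {
  vals <- c(daytime = unname(daytime), nocturnal = unname(nocturnal),
            severe = unname(severe))
  sig <- c(daytime = unname(daytime_significant),
           nocturnal = unname(nocturnal_significant),
           severe = unname(severe_significant))
  out <- list()
  for (cat in hypo_categories()) {
    check_number(vals[[cat]], paste0("rate_ratios.", cat, ".value"), 0,
                 strict_lower = TRUE)
    check_flag(sig[[cat]], paste0("rate_ratios.", cat, ".significant"))
    out[[cat]] <- list(value = vals[[cat]], significant = sig[[cat]])
  }
  structure(out, class = "hypo_rate_ratios")
}

ratio_values <- function(ratios) {
  vapply(hypo_categories(), function(cat) ratios[[cat]]$value, numeric(1))
}

ratio_flags <- function(ratios) {
  vapply(hypo_categories(), function(cat) ratios[[cat]]$significant, logical(1))
}

#' Per-event treatment costs of hypoglycaemia
#'
#' Cost of managing one event of each category, BGN/event, at the price year
#' of the analysis. `inflation_factor` records the price-year adjustment
#' already applied to the per-event costs (it is reporting metadata, not
#' applied again by the model).
#'
#' @param daytime,nocturnal,severe Per-event costs, BGN/event.
#' @param inflation_factor Positive price-year adjustment factor.
#' @return An object of class `event_costs` with a named `per_event` vector.
#' @export
event_costs <- function(daytime, nocturnal, severe, inflation_factor = 1) {
  check_number(daytime, "event_costs.daytime", 0)
  check_number(nocturnal, "event_costs.nocturnal", 0)
  check_number(severe, "event_costs.severe", 0)
  check_number(inflation_factor, "event_costs.inflation_factor", 0, strict_lower = TRUE)
  structure(list(per_event = c(daytime = daytime, nocturnal = nocturnal,
                               severe = severe),
                 inflation_factor = inflation_factor),
            class = "event_costs")
}

#' Utility inputs for QALY accounting
#'
#' Annual QALYs are a baseline utility minus per-event disutilities times
#' event counts, minus an optional mortality loss after severe events, plus
#' a flexible-dosing utility gain applied to the degludec arm only.
#'
#' @param baseline_utility Annual utility without hypoglycaemia, in (0, 1].
#' @param disutility_daytime,disutility_nocturnal,disutility_severe Utility
#'   loss per event of each category.
#' @param flexible_dosing_utility Annual utility gain from flexible dosing
#'   (degludec arm; default 0.006).
#' @param fraction_benefiting_flexible Proportion of patients gaining the
#'   flexible-dosing benefit, in [0, 1] (default 1).
#' @param mortality_risk_severe Probability of death per severe event
#'   (default 0.0112).
#' @param qaly_loss_per_death QALYs lost per death within the horizon
#'   (default 0: the mortality pathway is absorbed into the severe-event
#'   disutility unless explicitly switched on).
#' @return An object of class `utility_inputs` with a named `disutility`
#'   vector.
#' @export
utility_inputs <- function(baseline_utility,
                           disutility_daytime, disutility_nocturnal,
                           disutility_severe,
                           flexible_dosing_utility = 0.006,
                           fraction_benefiting_flexible = 1,
                           mortality_risk_severe = 0.0112,
                           qaly_loss_per_death = 0) {
  check_number(baseline_utility, "utilities.baseline_utility", 0, 1,
               strict_lower = TRUE)
  check_number(disutility_daytime, "utilities.disutility_daytime", 0)
  check_number(disutility_nocturnal, "utilities.disutility_nocturnal", 0)
  check_number(disutility_severe, "utilities.disutility_severe", 0)
  check_number(flexible_dosing_utility, "utilities.flexible_dosing_utility", 0)
  check_number(fraction_benefiting_flexible,
               "utilities.fraction_benefiting_flexible", 0, 1)
  check_number(mortality_risk_severe, "utilities.mortality_risk_severe", 0, 1)
  check_number(qaly_loss_per_death, "utilities.qaly_loss_per_death", 0)
  structure(list(baseline_utility = baseline_utility,
                 disutility = c(daytime = disutility_daytime,
                                nocturnal = disutility_nocturnal,
                                severe = disutility_severe),
                 flexible_dosing_utility = flexible_dosing_utility,
                 fraction_benefiting_flexible = fraction_benefiting_flexible,
                 mortality_risk_severe = mortality_risk_severe,
                 qaly_loss_per_death = qaly_loss_per_death),
            class = "utility_inputs")
}

#' Full model input set for one patient group
#'
#' Bundles the regimen, prices, glargine event rates, rate ratios, per-event
#' costs and utility inputs together with the analytic horizon. All nested
#' invariants are validated; the basal-oral group must have no bolus
#' component, the basal-bolus groups must have one (and then a bolus price).
#'
#' @param group One of [patient_groups()].
#' @param regimen An [insulin_regimen()].
#' @param prices A [unit_prices()].
#' @param glargine_rates A [hypo_rates()] for the glargine U100 arm.
#' @param rate_ratios A [hypo_rate_ratios()].
#' @param event_costs An [event_costs()].
#' @param utilities A [utility_inputs()].
#' @param horizon_years Positive horizon (default 1; integer if
#'   `discount_rate > 0`).
#' @param discount_rate Annual discount rate (default 0; the base case is a
#'   1-year horizon, so no discounting).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(group, regimen, prices, glargine_rates,
                             rate_ratios, event_costs, utilities,
                             horizon_years = 1, discount_rate = 0) {
  params <- structure(list(group = group, regimen = regimen, prices = prices,
                           glargine_rates = glargine_rates,
                           rate_ratios = rate_ratios,
                           event_costs = event_costs, utilities = utilities,
                           horizon_years = horizon_years,
                           discount_rate = discount_rate),
                      class = "model_parameters")
  validate_model_parameters(params)
}

#' Validate a `model_parameters` object
#'
#' Re-checks every invariant (used after scenario edits or probabilistic
#' draws). Errors name the offending field path.
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly-validated (returned unchanged).
#' @export
validate_model_parameters <- function(params) {
  if (!params$group %in% patient_groups())
    stop_field("group", paste("must be one of",
                              paste(patient_groups(), collapse = ", ")))
  stopifnot(inherits(params$regimen, "insulin_regimen"),
            inherits(params$prices, "unit_prices"),
            inherits(params$glargine_rates, "hypo_rates"),
            inherits(params$rate_ratios, "hypo_rate_ratios"),
            inherits(params$event_costs, "event_costs"),
            inherits(params$utilities, "utility_inputs"))
  # re-run the field checks (nested objects may have been edited in place)
  do.call(insulin_regimen, params$regimen[!vapply(params$regimen, is.null, logical(1))])
  do.call(unit_prices, params$prices[!vapply(params$prices, is.null, logical(1))])
  hypo_rates(params$glargine_rates[["daytime"]],
             params$glargine_rates[["nocturnal"]],
             params$glargine_rates[["severe"]])
  rv <- ratio_values(params$rate_ratios); rf <- ratio_flags(params$rate_ratios)
  hypo_rate_ratios(rv[["daytime"]], rv[["nocturnal"]], rv[["severe"]],
                   rf[["daytime"]], rf[["nocturnal"]], rf[["severe"]])
  pe <- params$event_costs$per_event
  event_costs(pe[["daytime"]], pe[["nocturnal"]], pe[["severe"]],
              params$event_costs$inflation_factor)
  u <- params$utilities
  utility_inputs(u$baseline_utility, u$disutility[["daytime"]],
                 u$disutility[["nocturnal"]], u$disutility[["severe"]],
                 u$flexible_dosing_utility, u$fraction_benefiting_flexible,
                 u$mortality_risk_severe, u$qaly_loss_per_death)
  if (identical(params$group, "T2DM_BOT") && has_bolus(params$regimen))
    stop_field("regimen.bolus_dose_glargine",
               "basal-oral therapy has no bolus component")
  if (!identical(params$group, "T2DM_BOT") && !has_bolus(params$regimen))
    stop_field("regimen.bolus_dose_glargine",
               "basal-bolus groups require a bolus dose")
  if (has_bolus(params$regimen) && is.null(params$prices$price_bolus))
    stop_field("prices.price_bolus", "required when a bolus component is present")
  check_number(params$horizon_years, "horizon_years", 0, strict_lower = TRUE)
  check_number(params$discount_rate, "discount_rate", 0)
  if (params$discount_rate > 0 &&
      abs(params$horizon_years - round(params$horizon_years)) > 1e-9)
    stop_field("horizon_years", "must be a whole number of years when discounting")
  params
}
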