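#' Degludec hypoglycaemia event rates from glargine rates and rate ratios
#'
#' Each category rate is the glargine U100 rate multiplied by the
#' significance-gated rate ratio; values are carried unrounded.
#'
#' @param glargine_rates A [hypo_rates()] object.
#' @param ratios A [hypo_rate_ratios()] object.
#' @return A `hypo_rates` object for the degludec arm.
#' @export
degludec_rates <- function(glargine_rates, ratios) {
  eff <- effective_ratio(ratio_values(ratios), ratio_flags(ratios))
  r <- unclass(glargine_rates) * eff
  hypo_rates(r[["daytime"]], r[["nocturnal"]], r[["severe"]])
}

#' Degludec daily doses from the glargine doses and dose ratios
#'
#' @param regimen An [insulin_regimen()].
#' @return List with `basal` and `bolus` doses in units/day (`bolus` is
#'   `NULL` for basal-oral therapy).
#' @export
degludec_doses <- function(regimen) {
  basal <- regimen$basal_dose_glargine *
    effective_ratio(regimen$basal_dose_ratio, regimen$basal_ratio_significant)
  bolus <- if (has_bolus(regimen))
    regimen$bolus_dose_glargine *
      effective_ratio(regimen$bolus_dose_ratio, regimen$bolus_ratio_significant)
  list(basal = basal, bolus = bolus)
}

#' Annual insulin acquisition cost
#'
#' @param basal Basal dose, units/day.
#' @param bolus Bolus dose, units/day, or `NULL`.
#' @param prices A [unit_prices()].
#' @param basal_price The basal price to use for this arm, BGN/unit.
#' @return Annual insulin cost, BGN/patient/year.
#' @export
annual_insulin_cost <- function(basal, bolus, prices, basal_price) {
  if (basal < 0 || (!is.null(bolus) && bolus < 0))
    stop("doses must be non-negative", call. = FALSE)
  bolus_part <- if (is.null(bolus)) 0 else bolus * prices$price_bolus
  (basal * basal_price + bolus_part) * prices$days_per_year
}

#' Annual hypoglycaemia management costs, by category
#'
#' @param rates A [hypo_rates()] object (the rates actually used in the arm).
#' @param costs An [event_costs()] object.
#' @return Named numeric vector (daytime, nocturnal, severe), BGN/year.
#' @export
annual_hypo_cost <- function(rates, costs) {
  unclass(rates) * costs$per_event
}

#' Annual quality-adjusted life years for one arm
#'
#' QALYs accrue as the baseline utility minus the per-event disutility times
#' the event rate in each category, minus an expected mortality loss after
#' severe events (`mortality_risk_severe * qaly_loss_per_death`, zero in the
#' base case), plus the flexible-dosing utility gain in the degludec arm.
#' A negative annual utility is floored at zero with a warning.
#'
#' @param rates A [hypo_rates()] object for the arm.
#' @param utilities A [utility_inputs()] object.
#' @param is_degludec Logical; apply the flexible-dosing utility gain?
#' @param horizon Horizon in years (default 1).
#' @param discount_rate Annual discount rate (default 0).
#' @return QALYs accumulated over the horizon.
#' @export
annual_qalys <- function(rates, utilities, is_degludec, horizon = 1,
                         discount_rate = 0) {
  annual <- utilities$baseline_utility -
    sum(unclass(rates) * utilities$disutility) -
    rates[["severe"]] * utilities$mortality_risk_severe *
      utilities$qaly_loss_per_death +
    (if (is_degludec)
       utilities$flexible_dosing_utility * utilities$fraction_benefiting_flexible
     else 0)
  if (annual < 0) {
    warning("annual utility below zero; floored at 0", call. = FALSE)
    annual <- 0
  }
  annual * discount_factor(horizon, discount_rate)
}

# cumulative (discounted) year-weights over the horizon; with no discounting
# this is just the horizon, so costs and QALYs scale identically and the
# ICER is horizon-invariant
discount_factor <- function(horizon, rate) {
  if (rate == 0) return(horizon)
  sum((1 + rate)^-(seq_len(round(horizon)) - 1))
}

#' Evaluate one treatment arm
#'
#' Composes the dose, rate, cost and QALY calculations for either arm and
#' accumulates them over the horizon (discounting, when nonzero, is applied
#' identically to costs and QALYs).
#'
#' @param params A [model_parameters()] object.
#' @param arm `"degludec"` or `"glargine"`.
#' @return An object of class `arm_outcome`: `insulin_cost`, `hypo_cost`
#'   (named by category), `total_cost`, `qalys` and the `event_rates`
#'   actually used.
#' @export
evaluate_arm <- function(params, arm = c("degludec", "glargine")) {
  arm <- match.arg(arm)
  if (arm == "degludec") {
    doses <- degludec_doses(params$regimen)
    rates <- degludec_rates(params$glargine_rates, params$rate_ratios)
    basal_price <- params$prices$price_basal_degludec
  } else {
    doses <- list(basal = params$regimen$basal_dose_glargine,
                  bolus = params$regimen$bolus_dose_glargine)
    rates <- params$glargine_rates
    basal_price <- params$prices$price_basal_glargine
  }
  df <- discount_factor(params$horizon_years, params$discount_rate)
  insulin_annual <- annual_insulin_cost(doses$basal, doses$bolus,
                                        params$prices, basal_price)
  hypo_annual <- annual_hypo_cost(rates, params$event_costs)
  qalys_annual <- annual_qalys(rates, params$utilities, arm == "degludec")
  insulin_cost <- insulin_annual * df
  hypo_cost <- hypo_annual * df
  structure(list(arm = arm,
                 insulin_cost = insulin_cost,
                 hypo_cost = hypo_cost,
                 total_cost = insulin_cost + sum(hypo_cost),
                 qalys = qalys_annual * df,
                 annual_total_cost = insulin_annual + sum(hypo_annual),
                 annual_qalys = qalys_annual,
                 event_rates = rates),
            class = "arm_outcome")
}

#' Incremental comparison of the degludec arm against glargine U100
#'
#' Classifies the incremental result on the cost-effectiveness plane:
#' `dominant` (no dearer, no less effective, at least one strict),
#' `dominated` (the mirror image), `quadrant_NE_icer` (dearer and more
#' effective: the ICER is the price of the health gain),
#' `quadrant_SW_icer` (cheaper and less effective: the ratio is reported but
#' flagged, it is not comparable to NE-quadrant ICERs), and `indeterminate`
#' (no difference in either dimension). The ICER is defined only in the two
#' ratio quadrants; division by a zero QALY difference never occurs.
#'
#' With no discounting both arms' costs and QALYs scale by the same
#' horizon weight, so the ICER is computed from the annual (per-year)
#' differences: it is bit-for-bit identical across horizons, not merely
#' equal up to rounding.
#'
#' @param deg,gla `arm_outcome` objects for degludec and glargine U100.
#' @return An object of class `comparison_result` with `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` when undefined) and `dominance`.
#' @export
compare <- function(deg, gla) {
  dc <- deg$total_cost - gla$total_cost
  dq <- deg$qalys - gla$qalys
  dominance <-
    if (dc <= 0 && dq >= 0 && (dc < 0 || dq > 0)) "dominant"
    else if (dc >= 0 && dq <= 0 && (dc > 0 || dq < 0)) "dominated"
    else if (dc > 0 && dq > 0) "quadrant_NE_icer"
    else if (dc < 0 && dq < 0) "quadrant_SW_icer"
    else "indeterminate"
  icer <- if (dominance %in% c("quadrant_NE_icer", "quadrant_SW_icer"))
    (deg$annual_total_cost - gla$annual_total_cost) /
      (deg$annual_qalys - gla$annual_qalys) else NA_real_
  structure(list(delta_cost = dc, delta_qalys = dq, icer = icer,
                 dominance = dominance),
            class = "comparison_result")
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = WTP * dQALY - dCost`; positive NMB means the intervention is
#' cost-effective at that threshold.
#'
#' @param result A `comparison_result`.
#' @param wtp Willingness to pay, BGN/QALY (vectorised).
#' @return Numeric NMB in BGN.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * result$delta_qalys - result$delta_cost
}

#' Evaluate both arms of one patient group and compare them
#'
#' @param params A [model_parameters()] object.
#' @return An object of class `group_evaluation`: `degludec` and `glargine`
#'   arm outcomes, the `comparison`, and the input `params`.
#' @export
evaluate_group <- function(params) {
  deg <- evaluate_arm(params, "degludec")
  gla <- evaluate_arm(params, "glargine")
  structure(list(degludec = deg, glargine = gla,
                 comparison = compare(deg, gla), params = params),
            class = "group_evaluation")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("incremental cost:  %10.2f BGN\n", x$delta_cost))
  cat(sprintf("incremental QALYs: %10.4f\n", x$delta_qalys))
  if (is.na(x$icer)) {
    cat(sprintf("ICER: undefined (%s)\n", x$dominance))
  } else {
    cat(sprintf("ICER: %.2f BGN/QALY (%s)\n", x$icer, x$dominance))
  }
  invisible(x)
}
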