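# Independent spreadsheet-style recomputation of one arm, written as flat
# arithmetic against the raw parameter fields (no package evaluation
# functions), used to cross-check evaluate_arm.
oracle_arm <- function(p, arm) {
  eff <- function(v, s) if (isTRUE(s)) v else 1
  cats <- c("daytime", "nocturnal", "severe")
  if (arm == "degludec") {
    basal <- p$regimen$basal_dose_glargine *
      eff(p$regimen$basal_dose_ratio, p$regimen$basal_ratio_significant)
    bolus <- if (is.null(p$regimen$bolus_dose_glargine)) NULL else
      p$regimen$bolus_dose_glargine *
        eff(p$regimen$bolus_dose_ratio, p$regimen$bolus_ratio_significant)
    basal_price <- p$prices$price_basal_degludec
    rates <- vapply(cats, function(cat)
      p$glargine_rates[[cat]] *
        eff(p$rate_ratios[[cat]]$value, p$rate_ratios[[cat]]$significant),
      numeric(1))
    flex <- p$utilities$flexible_dosing_utility *
      p$utilities$fraction_benefiting_flexible
  } else {
    basal <- p$regimen$basal_dose_glargine
    bolus <- p$regimen$bolus_dose_glargine
    basal_price <- p$prices$price_basal_glargine
    rates <- vapply(cats, function(cat) p$glargine_rates[[cat]], numeric(1))
    flex <- 0
  }
  w <- if (p$discount_rate == 0) p$horizon_years else
    sum((1 + p$discount_rate)^-(seq_len(round(p$horizon_years)) - 1))
  insulin <- (basal * basal_price +
                (if (is.null(bolus)) 0 else bolus * p$prices$price_bolus)) *
    p$prices$days_per_year
  hypo <- sum(rates * p$event_costs$per_event[cats])
  qaly <- p$utilities$baseline_utility -
    sum(rates * p$utilities$disutility[cats]) -
    rates[["severe"]] * p$utilities$mortality_risk_severe *
      p$utilities$qaly_loss_per_death + flex
  list(total_cost = (insulin + hypo) * w, qalys = max(qaly, 0) * w)
}

# calibration is deterministic; compute once per test run
local_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate()
    cache
  }
})

published <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- published_tables()
    cache
  }
})
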