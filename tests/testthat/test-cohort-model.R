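test_that("degludec doses follow the published dose-ratio arithmetic", {
  tab <- published()$insulin_use
  t1 <- insulin_regimen(28.11, 0.87, TRUE, 37.13, 0.88, TRUE)
  d <- degludec_doses(t1)
  expect_equal(d$basal, 28.11 * 0.87)            # 24.4557, printed 24.46
  expect_equal(d$bolus, 37.13 * 0.88)            # 32.6744, printed 32.67
  expect_equal(round(d$basal, 2), tab$T1DM_BB$basal_degludec_printed)
  expect_equal(round(d$bolus, 2), tab$T1DM_BB$bolus_degludec_printed)

  bb <- insulin_regimen(28.11, 1.08, TRUE, 37.13, 1.0, FALSE)
  d <- degludec_doses(bb)
  expect_equal(round(d$basal, 2), tab$T2DM_BB$basal_degludec_printed)  # 30.36
  expect_identical(d$bolus, 37.13)               # non-significant ratio: unchanged

  bot <- insulin_regimen(28.11, 0.90, TRUE)
  d <- degludec_doses(bot)
  expect_equal(round(d$basal, 2), tab$T2DM_BOT$basal_degludec_printed) # 25.30
  expect_null(d$bolus)
})

test_that("degludec event rates follow the published rate-ratio arithmetic", {
  t1 <- degludec_rates(hypo_rates(30.42, 8.52, 3.20),
                       hypo_rate_ratios(nocturnal = 0.83,
                                        nocturnal_significant = TRUE))
  expect_equal(unclass(t1),
               c(daytime = 30.42, nocturnal = 8.52 * 0.83, severe = 3.20))
  expect_equal(round(t1[["nocturnal"]], 2), 7.07)

  bot <- degludec_rates(hypo_rates(23.12, 13.38, 0.10),
                        hypo_rate_ratios(nocturnal = 0.64, severe = 0.14,
                                         nocturnal_significant = TRUE,
                                         severe_significant = TRUE))
  expect_equal(bot[["severe"]], 0.014)           # printed as 0.01

  # all ratios non-significant: rates pass through unchanged
  r <- hypo_rates(1.2, 3.4, 0.5)
  expect_identical(unclass(degludec_rates(r, hypo_rate_ratios(0.5, 0.7, 0.9))),
                   unclass(r))
})

test_that("annual cost pieces behave linearly and at zero", {
  pr <- unit_prices(0.056, 0.086, 0.045)
  expect_equal(annual_insulin_cost(0, 0, pr, 0.056), 0)
  expect_equal(annual_insulin_cost(28.11, NULL, pr, 0.056),
               28.11 * 0.056 * 365)
  expect_equal(annual_insulin_cost(10, 20, pr, 0.086),
               (10 * 0.086 + 20 * 0.045) * 365)
  expect_error(annual_insulin_cost(-1, 0, pr, 0.056), "non-negative")

  ec <- event_costs(0.65, 33.19, 508.10)
  expect_equal(annual_hypo_cost(hypo_rates(0, 0, 0), ec),
               c(daytime = 0, nocturnal = 0, severe = 0))
  expect_equal(annual_hypo_cost(hypo_rates(2, 3, 0.5), ec),
               c(daytime = 2 * 0.65, nocturnal = 3 * 33.19,
                 severe = 0.5 * 508.10))
})

test_that("QALY accrual matches its definition and floors at zero", {
  u <- utility_inputs(0.8, 0.004, 0.006, 0.07, flexible_dosing_utility = 0)
  expect_equal(annual_qalys(hypo_rates(0, 0, 0), u, FALSE), 0.8)
  u2 <- utility_inputs(0.8, 0.004, 0.006, 0.07)
  expect_equal(annual_qalys(hypo_rates(10, 5, 1), u2, TRUE),
               0.8 - (10 * 0.004 + 5 * 0.006 + 1 * 0.07) + 0.006)
  # mortality pathway enters only when a QALY loss per death is set
  u3 <- utility_inputs(0.8, 0, 0, 0, flexible_dosing_utility = 0,
                       qaly_loss_per_death = 0.4)
  expect_equal(annual_qalys(hypo_rates(0, 0, 2), u3, FALSE),
               0.8 - 2 * 0.0112 * 0.4)
  u4 <- utility_inputs(0.1, 0.01, 0.01, 0.1, flexible_dosing_utility = 0)
  expect_warning(q <- annual_qalys(hypo_rates(50, 50, 5), u4, FALSE),
                 "floored")
  expect_identical(q, 0)
})

test_that("arm totals are exactly additive and match an independent recomputation", {
  for (s in 1:100) {
    p <- random_parameters(synthetic_spec(s))
    for (arm in c("degludec", "glargine")) {
      out <- evaluate_arm(p, arm)
      expect_identical(out$total_cost, out$insulin_cost + sum(out$hypo_cost))
      ora <- oracle_arm(p, arm)
      expect_equal(out$total_cost, ora$total_cost, tolerance = 1e-9)
      expect_equal(out$qalys, ora$qalys, tolerance = 1e-9)
    }
  }
})

test_that("glargine arm with unit ratios mirrors degludec up to flexible dosing", {
  p <- random_parameters(synthetic_spec(21))
  p <- apply_scenario(p, scenario_spec("null", list(
    regimen.basal_dose_ratio = 1,
    regimen.bolus_dose_ratio = list(set = 1, optional = TRUE),
    rate_ratios.daytime.value = 1, rate_ratios.daytime.significant = TRUE,
    rate_ratios.nocturnal.value = 1, rate_ratios.nocturnal.significant = TRUE,
    rate_ratios.severe.value = 1, rate_ratios.severe.significant = TRUE,
    prices.price_basal_degludec = p$prices$price_basal_glargine)))
  deg <- evaluate_arm(p, "degludec")
  gla <- evaluate_arm(p, "glargine")
  expect_equal(deg$total_cost, gla$total_cost)
  expect_equal(deg$qalys - gla$qalys,
               p$utilities$flexible_dosing_utility *
                 p$utilities$fraction_benefiting_flexible)

  # and with the flexible utility removed the comparison is indeterminate
  p0 <- apply_scenario(p, scenario_spec("noflex",
                                        list(utilities.flexible_dosing_utility = 0)))
  cmp <- evaluate_group(p0)$comparison
  expect_identical(cmp$dominance, "indeterminate")
  expect_identical(cmp$delta_cost, 0)
  expect_true(is.na(cmp$icer))
})

test_that("dominance classes cover the cost-effectiveness plane", {
  arm <- function(cost, q) structure(list(total_cost = cost, qalys = q,
                                          annual_total_cost = cost,
                                          annual_qalys = q),
                                     class = "arm_outcome")
  expect_identical(compare(arm(95, 0.51), arm(100, 0.5))$dominance, "dominant")
  expect_true(is.na(compare(arm(95, 0.51), arm(100, 0.5))$icer))
  expect_identical(compare(arm(105, 0.49), arm(100, 0.5))$dominance, "dominated")
  expect_identical(compare(arm(100, 0.5), arm(100, 0.5))$dominance, "indeterminate")
  ne <- compare(arm(110, 0.52), arm(100, 0.5))
  expect_identical(ne$dominance, "quadrant_NE_icer")
  expect_equal(ne$icer, 10 / 0.02)
  sw <- compare(arm(90, 0.48), arm(100, 0.5))
  expect_identical(sw$dominance, "quadrant_SW_icer")
  expect_equal(sw$icer, -10 / -0.02)
  # boundary: cheaper, equal QALYs is dominant, not SW
  expect_identical(compare(arm(90, 0.5), arm(100, 0.5))$dominance, "dominant")
})

test_that("net monetary benefit follows its definition", {
  arm <- function(cost, q) structure(list(total_cost = cost, qalys = q,
                                          annual_total_cost = cost,
                                          annual_qalys = q),
                                     class = "arm_outcome")
  cmp <- compare(arm(117.35, 0.5435), arm(100, 0.5))  # printed increments
  expect_equal(net_monetary_benefit(cmp, 39619), 39619 * 0.0435 - 17.35,
               tolerance = 1e-9)                       # 1706.08
  expect_equal(net_monetary_benefit(cmp, cmp$icer), 0, tolerance = 1e-9)
  expect_equal(net_monetary_benefit(cmp, 0), -cmp$delta_cost)
  expect_error(net_monetary_benefit(cmp, -1), "non-negative")
})

test_that("the ICER is invariant to the horizon and to symmetric discounting", {
  cal <- local_calibration()
  for (group in patient_groups()) {
    p <- cal$parameters[[group]]
    base <- evaluate_group(p)$comparison
    p5 <- apply_scenario(p, scenario_spec("h5", list(horizon_years = 5)))
    five <- evaluate_group(p5)$comparison
    expect_identical(five$icer, base$icer)    # bit-for-bit
    expect_equal(five$delta_cost, 5 * base$delta_cost)
    # discounting applied to costs and QALYs alike also cancels
    pd <- apply_scenario(p, scenario_spec("disc", list(horizon_years = 5,
                                                       discount_rate = 0.03)))
    expect_identical(evaluate_group(pd)$comparison$icer, base$icer)
  }
})

test_that("raising a degludec rate ratio never lowers the ICER while QALY gain stays positive", {
  cal <- local_calibration()
  p <- cal$parameters$T2DM_BOT
  last <- -Inf
  for (ratio in seq(0.3, 0.99, by = 0.05)) {
    pr <- apply_scenario(p, scenario_spec("sweep", list(
      rate_ratios.nocturnal.value = ratio,
      rate_ratios.nocturnal.significant = TRUE)))
    cmp <- evaluate_group(pr)$comparison
    expect_gt(cmp$delta_qalys, 0)
    if (!is.na(cmp$icer)) {
      expect_gte(cmp$icer, last)
      last <- cmp$icer
    }
  }
})
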