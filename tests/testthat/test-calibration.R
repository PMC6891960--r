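test_that("basal unit prices are identified by the basal-oral insulin cells", {
  tab <- published()
  prices <- solve_unit_prices(tab)
  # direct division oracles: annual cell / (dose x 365)
  expect_equal(prices$T2DM_BOT$price_basal_glargine,
               574.23 / (28.11 * 365))                 # ~0.05597 BGN/unit
  expect_equal(prices$T2DM_BOT$price_basal_degludec,
               794.93 / (28.11 * 0.90 * 365))          # ~0.08609 BGN/unit
  expect_equal(round(prices$T2DM_BOT$price_basal_glargine, 5), 0.05597)
  expect_equal(round(prices$T2DM_BOT$price_basal_degludec, 5), 0.08609)
  # the glargine basal price is shared across groups (same dose, same cell)
  for (g in patient_groups())
    expect_equal(prices[[g]]$price_basal_glargine,
                 prices$T2DM_BOT$price_basal_glargine)
})

test_that("price solving is linear in the printed insulin cells", {
  tab <- published()
  doubled <- tab
  for (g in patient_groups())
    doubled$annual_results[[g]]$insulin <-
      lapply(tab$annual_results[[g]]$insulin, `*`, 2)
  p1 <- solve_unit_prices(tab)
  p2 <- solve_unit_prices(doubled)
  for (g in patient_groups()) {
    expect_equal(p2[[g]]$price_basal_glargine, 2 * p1[[g]]$price_basal_glargine)
    expect_equal(p2[[g]]$price_basal_degludec, 2 * p1[[g]]$price_basal_degludec)
    if (!is.null(p1[[g]]$price_bolus))
      expect_equal(p2[[g]]$price_bolus, 2 * p1[[g]]$price_bolus)
  }
})

test_that("per-event costs solve by level division and agree across arms", {
  tab <- published()
  costs <- solve_event_costs(tab)
  expect_equal(costs$T1DM_BB$per_event[["nocturnal"]], 277.60 / 8.52)  # ~32.58
  expect_equal(round(costs$T2DM_BOT$per_event[["nocturnal"]], 2), 33.18)
  # close to the published 33.19 per-event cost
  expect_lt(abs(costs$T2DM_BOT$per_event[["nocturnal"]] - 33.19) / 33.19, 0.001)
  disc <- attr(costs, "discrepancy")
  for (g in patient_groups())
    expect_true(all(disc[[g]] < 0.002, na.rm = TRUE))
  # severe per-event cost spans the published-cell inconsistency 499.0-507.8
  sev <- vapply(costs, function(ec) ec$per_event[["severe"]], numeric(1))
  expect_equal(unname(round(range(sev), 1)), c(499.0, 507.8))
})

test_that("cross-group parameter spreads are reported, small for costs, ~2.8% for the bolus price", {
  tab <- published()
  spread_costs <- attr(solve_event_costs(tab), "spread")
  expect_true(all(spread_costs < 0.025))
  spread_prices <- attr(solve_unit_prices(tab), "spread")
  expect_equal(spread_prices[["price_basal_glargine"]], 0)
  expect_lt(spread_prices[["price_basal_degludec"]], 0.025)
  # the printed cells imply bolus prices 2.7-2.8% apart between the two
  # basal-bolus groups; frozen against the direct division oracle
  bolus_t1 <- (1180.11 - 574.23) / (37.13 * 365)
  bolus_bb <- (1196.94 - 574.23) / (37.13 * 365)
  expect_equal(spread_prices[["price_bolus"]],
               (bolus_bb - bolus_t1) / mean(c(bolus_t1, bolus_bb)))
  expect_lt(spread_prices[["price_bolus"]], 0.03)
})

test_that("disutilities solve triangularly from the QALY increments", {
  tab <- published()
  d <- solve_disutilities(tab)
  # step 1: only the nocturnal rate differs in the type 1 group
  d_noct <- (0.0154 - 0.006) / (8.52 - 8.52 * 0.83)
  expect_equal(d[["nocturnal"]], d_noct)              # ~0.00649
  # step 2: the basal-bolus type 2 group adds the daytime difference
  d_day <- (0.0413 - 0.006 - (8.52 - 8.52 * 0.75) * d_noct) /
    (30.42 - 30.42 * 0.83)
  expect_equal(d[["daytime"]], d_day)                 # ~0.00415
  # step 3: the basal-oral group adds the severe difference
  d_sev <- (0.0435 - 0.006 - (13.38 - 13.38 * 0.64) * d_noct) /
    (0.10 - 0.10 * 0.14)
  expect_equal(d[["severe"]], d_sev)                  # ~0.0726
  expect_equal(round(unname(d), 5), c(0.00415, 0.00649, 0.07255))
  expect_true(all(d > 0 & d < 0.15))

  # an inflated flexible-utility assumption drives a disutility negative
  expect_error(solve_disutilities(tab, flexible_utility = 0.05),
               "inconsistent flexible-utility")
})

test_that("baseline utilities reconcile across both arms", {
  tab <- published()
  d <- solve_disutilities(tab)
  base <- solve_baseline_utilities(tab, d)
  expect_equal(round(base[["T1DM_BB"]], 3), 0.971)
  expect_true(all(attr(base, "arm_disagreement") < 0.002))
  expect_true(all(attr(base, "valid")))
  # direct arithmetic oracle for the glargine arm
  expect_equal(base[["T1DM_BB"]],
               0.5568 + 30.42 * d[["daytime"]] + 8.52 * d[["nocturnal"]] +
                 3.20 * d[["severe"]])
})

test_that("the price-year factor is the category-wise cost ratio", {
  inf <- solve_inflation_factor(published())
  expect_equal(inf$per_category[["severe"]], 508.10 / 514.36)   # ~0.98783
  expect_equal(inf$per_category[["nocturnal"]], 33.19 / 33.60)  # ~0.98780
  expect_equal(inf$per_category[["daytime"]], 0.65 / 0.66)
  expect_lt(inf$spread, 0.01)
  same <- published()
  same$event_cost_per_event$cost_2014 <- same$event_cost_per_event$cost_2018
  expect_equal(solve_inflation_factor(same)$per_category,
               c(daytime = 1, nocturnal = 1, severe = 1))
})

test_that("the forward model reproduces every published cost and QALY cell", {
  cal <- local_calibration()
  cells <- cal$residuals[cal$residuals$row != "icer", ]
  expect_equal(nrow(cells), 3 * 2 * 7)
  expect_true(all(cells$rel_error < 0.002))
  expect_true(all(cal$icers$rel_error < 0.01))
})

test_that("using the published per-event costs instead of calibrated ones stays within 2.5%", {
  tab <- published()
  cal <- local_calibration()
  for (group in patient_groups()) {
    p <- cal$parameters[[group]]
    p$event_costs <- event_costs(tab$event_cost_per_event$cost_2018$daytime,
                                 tab$event_cost_per_event$cost_2018$nocturnal,
                                 tab$event_cost_per_event$cost_2018$severe)
    ev <- evaluate_group(p)
    for (arm in c("degludec", "glargine"))
      for (cat in hypo_categories()) {
        pub <- tab$annual_results[[group]][[cat]][[arm]]
        expect_lt(abs(ev[[arm]]$hypo_cost[[cat]] - pub) / pub, 0.025)
      }
  }
})

test_that("scaling all cost cells scales prices, costs and the ICER cost side", {
  tab <- published()
  k <- 3.7
  scaled <- tab
  for (g in patient_groups())
    for (row in c("insulin", "hypo_total", "daytime", "nocturnal", "severe",
                  "total"))
      scaled$annual_results[[g]][[row]] <-
        lapply(tab$annual_results[[g]][[row]], `*`, k)
  cal1 <- calibrate(tab)
  calk <- calibrate(scaled)
  for (g in patient_groups()) {
    expect_equal(calk$parameters[[g]]$event_costs$per_event,
                 k * cal1$parameters[[g]]$event_costs$per_event)
    expect_equal(calk$parameters[[g]]$prices$price_basal_degludec,
                 k * cal1$parameters[[g]]$prices$price_basal_degludec)
  }
  expect_equal(calk$icers$modelled, k * cal1$icers$modelled)
})

test_that("a perturbed published cell is flagged as a calibration failure", {
  tab <- published()
  tab$annual_results$T1DM_BB$insulin$degludec <-
    tab$annual_results$T1DM_BB$insulin$degludec * 1.10
  cal <- calibrate(tab)
  # the insulin price solve absorbs its own cell, but the totals no longer fit
  expect_gt(max(cal$residuals$rel_error[cal$residuals$row == "total"]), 0.002)
})

test_that("the calibration report writes and its configs reload cleanly", {
  cal <- local_calibration()
  dir <- withr::local_tempdir()
  files <- write_calibration(cal, dir)
  expect_true(all(file.exists(files)))
  report <- jsonlite::read_json(file.path(dir, "calibration_report.json"))
  expect_lt(report$max_residual, 0.002)
  for (group in patient_groups()) {
    cfg <- file.path(dir, sprintf("parameters_%s.yaml", tolower(group)))
    p <- load_parameters(cfg)
    expect_equal(p, cal$parameters[[group]], tolerance = 1e-12)
  }
})
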