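test_that("distribution specs enforce family support", {
  expect_s3_class(dist_spec("event_costs.per_event.severe", "gamma", 508, 0.2),
                  "dist_spec")
  expect_error(dist_spec("x", "gamma", -1, 0.2), "positive central")
  expect_error(dist_spec("x", "beta", 1.2, 0.2), "in \\(0, 1\\)")
  expect_error(dist_spec("x", "beta", 0.9, 0.9), "cannot match")
})

test_that("all-fixed specs reproduce the base parameters exactly", {
  p <- local_calibration()$parameters$T2DM_BOT
  specs <- list(dist_spec("rate_ratios.nocturnal.value", "fixed", 0.64),
                dist_spec("event_costs.per_event.severe", "fixed",
                          p$event_costs$per_event[["severe"]]))
  draws <- sample_parameters(p, specs, n = 5, seed = 3)
  for (i in 1:5) {
    pi <- draw_parameters(draws, i)
    expect_equal(pi$event_costs$per_event, p$event_costs$per_event)
    expect_equal(pi$rate_ratios$nocturnal$value, 0.64)
  }
})

test_that("draws converge to the central value as dispersion vanishes", {
  p <- local_calibration()$parameters$T2DM_BOT
  for (cv in c(1e-4, 1e-6)) {
    specs <- list(dist_spec("rate_ratios.nocturnal.value", "lognormal",
                            0.64, cv))
    draws <- sample_parameters(p, specs, n = 200, seed = 5)
    expect_equal(max(abs(draws$values[, 1] - 0.64)), 0, tolerance = 10 * cv)
  }
})

test_that("moment matching holds: gamma sample mean within 1% of the central value", {
  p <- local_calibration()$parameters$T2DM_BOT
  specs <- list(dist_spec("event_costs.per_event.nocturnal", "gamma",
                          33.18, 0.2))
  draws <- sample_parameters(p, specs, n = 10000, seed = 11)
  expect_equal(mean(draws$values[, 1]), 33.18, tolerance = 0.01)
  # lognormal and beta are moment-matched the same way
  specs2 <- list(dist_spec("rate_ratios.nocturnal.value", "lognormal", 0.64, 0.15),
                 dist_spec("utilities.flexible_dosing_utility", "beta", 0.006, 0.2))
  draws2 <- sample_parameters(p, specs2, n = 10000, seed = 11)
  expect_equal(unname(colMeans(draws2$values)), c(0.64, 0.006), tolerance = 0.01)
})

test_that("per-parameter streams are unperturbed by adding parameters", {
  p <- local_calibration()$parameters$T2DM_BOT
  s1 <- list(dist_spec("rate_ratios.nocturnal.value", "lognormal", 0.64, 0.15))
  s2 <- c(s1, list(dist_spec("event_costs.per_event.severe", "gamma", 507, 0.2)))
  d1 <- sample_parameters(p, s1, n = 100, seed = 9)
  d2 <- sample_parameters(p, s2, n = 100, seed = 9)
  expect_identical(d1$values[, "rate_ratios.nocturnal.value"],
                   d2$values[, "rate_ratios.nocturnal.value"])
})

test_that("the acceptability curve follows its definition", {
  one <- data.frame(delta_cost = 10, delta_qalys = 0.01)
  curve <- ceac(one, c(0, 500, 999, 1001, 5000))
  expect_equal(curve$probability, c(0, 0, 0, 1, 1))   # step at the ICER

  set.seed(42)
  cloud <- data.frame(delta_cost = rnorm(5000, 10, 40),
                      delta_qalys = rnorm(5000, 0.01, 0.002))
  # at WTP 0 the probability is the fraction of cost-saving draws
  expect_equal(ceac(cloud, 0)$probability, mean(cloud$delta_cost < 0))
  # far beyond every draw's ratio it approaches P(dQALY > 0)
  expect_equal(ceac(cloud, 1e9)$probability, mean(cloud$delta_qalys > 0))
  # symmetric cloud centred on the base increments: ~50% at the base ICER
  expect_equal(ceac(cloud, 10 / 0.01)$probability, 0.5, tolerance = 0.03)
  # monotone non-decreasing when every draw gains QALYs
  pos <- cloud[cloud$delta_qalys > 0, ]
  curve <- ceac(pos, seq(0, 50000, by = 500))
  expect_true(all(diff(curve$probability) >= 0))
  expect_error(ceac(cloud[0, ], 0), "no draws")
})

test_that("a PSA run is reproducible and degenerates to the deterministic result", {
  p <- local_calibration()$parameters$T2DM_BOT
  a <- run_psa(p, n = 400, seed = 17)
  b <- run_psa(p, n = 400, seed = 17)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  expect_identical(a$probability_at_threshold, b$probability_at_threshold)
  expect_true(39619 %in% a$ceac$wtp)

  # zero-dispersion PSA equals the deterministic evaluation
  det <- evaluate_group(p)$comparison
  frozen <- run_psa(p, default_psa_specs(p, 0, 0, 0), n = 50, seed = 1)
  expect_equal(frozen$mean_delta_cost, det$delta_cost, tolerance = 1e-6)
  expect_equal(frozen$mean_delta_qalys, det$delta_qalys, tolerance = 1e-6)
  expect_equal(frozen$icer_of_means, det$icer, tolerance = 1e-6)
  # and its CEAC is the step function of the deterministic ICER
  expect_equal(frozen$ceac$probability,
               as.numeric(frozen$ceac$wtp > det$icer))
})

test_that("every PSA draw is a valid parameter set", {
  p <- local_calibration()$parameters$T1DM_BB
  draws <- sample_parameters(p, default_psa_specs(p), n = 50, seed = 23)
  for (i in 1:50) expect_s3_class(draw_parameters(draws, i), "model_parameters")
})

test_that("acceptability CSVs are byte-identical across reruns", {
  p <- local_calibration()$parameters$T2DM_BOT
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ceac(run_psa(p, n = 300, seed = 31), f1)
  write_ceac(run_psa(p, n = 300, seed = 31), f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1, n = 1)
  expect_identical(header, "wtp,probability")
})
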