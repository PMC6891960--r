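#' Distribution assignment for one uncertain parameter
#'
#' Families are restricted to the parameter's support: `gamma` or
#' `lognormal` for non-negative quantities (costs, doses, ratios), `beta`
#' for quantities bounded in (0, 1) (utilities, disutilities,
#' probabilities), `fixed` for parameters held at their central value.
#' Dispersion is given as a coefficient of variation; moments are matched
#' so that the mean of each family equals the central value. A CV of 0
#' degenerates to `fixed`.
#'
#' @param path Dot-separated parameter path (as in [scenario_spec()]).
#' @param family One of `"gamma"`, `"lognormal"`, `"beta"`, `"fixed"`.
#' @param central Central value (the deterministic base case).
#' @param cv Coefficient of variation (default 0).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(path, family = c("fixed", "gamma", "lognormal", "beta"),
                      central, cv = 0) {
  family <- match.arg(family)
  check_number(central, path)
  check_number(cv, paste0(path, ".cv"), 0)
  if (family %in% c("gamma", "lognormal") && central <= 0)
    stop_field(path, sprintf("%s requires a positive central value", family))
  if (family == "beta") {
    if (central <= 0 || central >= 1)
      stop_field(path, "beta requires a central value in (0, 1)")
    if (cv^2 >= (1 - central) / central)
      stop_field(path, "beta cannot match this mean and CV")
  }
  structure(list(path = path, family = family, central = central, cv = cv),
            class = "dist_spec")
}

#' Default probabilistic sensitivity distributions for a parameter set
#'
#' The source analysis does not publish its distribution families or
#' dispersions, so these defaults encode conventional health-economic
#' choices: gamma (CV 0.20) on per-event costs, lognormal (CV 0.15) on dose
#' ratios and hypoglycaemia rate ratios, beta (CV 0.20) on per-event
#' disutilities and the flexible-dosing utility; unit prices, baseline
#' utility and the glargine event rates are held fixed. Non-significant
#' ratios are sampled around 1 rather than pinned at 1, so the uncertainty
#' of a no-difference assumption is retained (an interpretive choice: with
#' those ratios fixed the acceptability curve would understate decision
#' uncertainty).
#'
#' @param params A [model_parameters()] object.
#' @param cv_costs,cv_ratios,cv_utilities Coefficients of variation.
#' @return Named list of [dist_spec()]s (names are parameter paths).
#' @export
default_psa_specs <- function(params, cv_costs = 0.20, cv_ratios = 0.15,
                              cv_utilities = 0.20) {
  specs <- list()
  add <- function(spec) specs[[spec$path]] <<- spec
  eff <- effective_ratio(ratio_values(params$rate_ratios),
                         ratio_flags(params$rate_ratios))
  for (cat in hypo_categories()) {
    add(dist_spec(sprintf("rate_ratios.%s.value", cat), "lognormal",
                  eff[[cat]], cv_ratios))
    cost <- params$event_costs$per_event[[cat]]
    if (cost > 0)
      add(dist_spec(sprintf("event_costs.per_event.%s", cat), "gamma",
                    cost, cv_costs))
    d <- params$utilities$disutility[[cat]]
    if (d > 0 && d < 1)
      add(dist_spec(sprintf("utilities.disutility.%s", cat), "beta",
                    d, cv_utilities))
  }
  add(dist_spec("regimen.basal_dose_ratio", "lognormal",
                effective_ratio(params$regimen$basal_dose_ratio,
                                params$regimen$basal_ratio_significant),
                cv_ratios))
  if (has_bolus(params$regimen))
    add(dist_spec("regimen.bolus_dose_ratio", "lognormal",
                  effective_ratio(params$regimen$bolus_dose_ratio,
                                  params$regimen$bolus_ratio_significant),
                  cv_ratios))
  flex <- params$utilities$flexible_dosing_utility
  if (flex > 0 && flex < 1)
    add(dist_spec("utilities.flexible_dosing_utility", "beta", flex,
                  cv_utilities))
  specs
}

# a ratio/dose path carries a significance flag: sampled values are applied
# directly, so the companion flag is forced TRUE in each draw
companion_flag <- function(path) {
  if (grepl("^rate_ratios\\.[a-z]+\\.value$", path))
    return(sub("value$", "significant", path))
  if (path == "regimen.basal_dose_ratio") return("regimen.basal_ratio_significant")
  if (path == "regimen.bolus_dose_ratio") return("regimen.bolus_ratio_significant")
  NULL
}

# deterministic sub-seed per (seed, parameter path): one stream per
# parameter, so adding a parameter does not perturb the others' draws
param_stream_seed <- function(seed, path) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(path)) h <- (h * 31 + c) %% m
  as.integer((h + (seed %% m) * 104729) %% m)
}

draw_one <- function(spec, n, seed) {
  if (spec$family == "fixed" || spec$cv == 0)
    return(rep(spec$central, n))
  set.seed(param_stream_seed(seed, spec$path))
  m <- spec$central; cv <- spec$cv
  out <- switch(spec$family,
    gamma = {
      shape <- 1 / cv^2
      stats::rgamma(n, shape = shape, rate = shape / m)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    beta = {
      v <- (cv * m)^2
      a <- m * (m * (1 - m) / v - 1)
      b <- a * (1 - m) / m
      stats::rbeta(n, a, b)
    })
  # resample draws that violate the parameter support (degenerate RNG tail
  # cases); capped, with a warning if the cap is hit
  lower <- 0; upper <- if (spec$family == "beta") 1 else Inf
  for (i in seq_len(100L)) {
    bad <- !is.finite(out) | out <= lower | out >= upper
    if (!any(bad)) break
    out[bad] <- draw_one_tail(spec, sum(bad))
    if (i == 100L) warning(sprintf("resampling cap reached for %s", spec$path),
                           call. = FALSE)
  }
  out
}

draw_one_tail <- function(spec, n) {
  m <- spec$central; cv <- spec$cv
  switch(spec$family,
    gamma = stats::rgamma(n, shape = 1 / cv^2, rate = (1 / cv^2) / m),
    lognormal = {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
    },
    beta = {
      v <- (cv * m)^2
      a <- m * (m * (1 - m) / v - 1)
      stats::rbeta(n, a, a * (1 - m) / m)
    })
}

#' Draw parameter values for probabilistic sensitivity analysis
#'
#' Reproducible given the seed. Each parameter is drawn from its own
#' deterministic stream (seeded from the analysis seed and the parameter
#' path), so extending the specification with a new parameter leaves the
#' other parameters' draws unchanged.
#'
#' @param params Base-case [model_parameters()].
#' @param specs Named list of [dist_spec()]s.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return An object of class `psa_draws`: `values` (n x parameters
#'   matrix), `specs`, `params`, `n`, `seed`.
#' @export
sample_parameters <- function(params, specs, n, seed) {
  stopifnot(n >= 1)
  cols <- lapply(specs, draw_one, n = n, seed = seed)
  values <- do.call(cbind, cols)
  colnames(values) <- vapply(specs, `[[`, character(1), "path")
  structure(list(values = values, specs = specs, params = params,
                 n = n, seed = seed),
            class = "psa_draws")
}

#' Materialise one draw as a full parameter set
#'
#' @param draws A `psa_draws` object.
#' @param i Draw index.
#' @return A validated `model_parameters` object.
#' @export
draw_parameters <- function(draws, i) {
  validate_model_parameters(apply_draw(draws$params, draws$values, i))
}

apply_draw <- function(params, values, i) {
  out <- params
  for (path in colnames(values)) {
    out <- set_param(out, path, unname(values[i, path]))
    flag <- companion_flag(path)
    if (!is.null(flag)) out <- set_param(out, flag, TRUE)
  }
  out
}

#' Cost-effectiveness acceptability curve from incremental draws
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of draws with positive net monetary benefit
#' (`wtp * dQALY - dCost > 0`).
#'
#' @param draws Data frame with columns `delta_cost` and `delta_qalys`.
#' @param wtp_grid Numeric vector of willingness-to-pay values, BGN/QALY.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (nrow(draws) == 0L) stop("no draws", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(w * draws$delta_qalys - draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Default willingness-to-pay grid
#'
#' 0 to 100,000 BGN/QALY in 2,500 BGN steps, always including the Bulgarian
#' threshold of 39,619 BGN/QALY (three times GDP per capita).
#'
#' @param threshold Threshold to include (default 39,619).
#' @return Sorted numeric vector.
#' @export
default_wtp_grid <- function(threshold = 39619) {
  sort(unique(c(seq(0, 100000, by = 2500), threshold)))
}

#' Run a probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the model by Monte Carlo:
#' samples the parameters, evaluates both arms for every draw, and
#' summarises the incremental cost and QALY cloud as a cost-effectiveness
#' acceptability curve and net-monetary-benefit summaries. Deterministic
#' given the seed.
#'
#' @param params Base-case [model_parameters()].
#' @param specs Named list of [dist_spec()]s (default
#'   [default_psa_specs()]).
#' @param n Number of draws (default 10,000).
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid (default [default_wtp_grid()]).
#' @param threshold Threshold at which the headline probability is reported
#'   (default 39,619 BGN/QALY; always added to the grid).
#' @return An object of class `psa_result`: `draws` (data frame of
#'   `delta_cost`, `delta_qalys`), `ceac`, `mean_delta_cost`,
#'   `mean_delta_qalys`, `icer_of_means`, `threshold`,
#'   `probability_at_threshold`, `mean_nmb_at_threshold`, `n`, `seed`.
#' @export
run_psa <- function(params, specs = default_psa_specs(params), n = 10000,
                    seed = 1, wtp_grid = default_wtp_grid(threshold),
                    threshold = 39619) {
  sampled <- sample_parameters(params, specs, n, seed)
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    p <- apply_draw(params, sampled$values, i)
    cmp <- compare(evaluate_arm(p, "degludec"), evaluate_arm(p, "glargine"))
    dc[i] <- cmp$delta_cost
    dq[i] <- cmp$delta_qalys
  }
  draws <- data.frame(delta_cost = dc, delta_qalys = dq)
  grid <- sort(unique(c(wtp_grid, threshold)))
  curve <- ceac(draws, grid)
  nmb <- threshold * dq - dc
  structure(list(draws = draws,
                 ceac = curve,
                 mean_delta_cost = mean(dc),
                 mean_delta_qalys = mean(dq),
                 icer_of_means = mean(dc) / mean(dq),
                 threshold = threshold,
                 probability_at_threshold = mean(nmb > 0),
                 mean_nmb_at_threshold = mean(nmb),
                 n = n, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean incremental cost:  %9.2f BGN\n", x$mean_delta_cost))
  cat(sprintf("  mean incremental QALYs: %9.4f\n", x$mean_delta_qalys))
  cat(sprintf("  ICER of means: %.2f BGN/QALY\n", x$icer_of_means))
  cat(sprintf("  P(cost-effective at %s BGN/QALY): %.3f\n",
              format(x$threshold, big.mark = ","),
              x$probability_at_threshold))
  invisible(x)
}

#' Write an acceptability curve as CSV
#'
#' Fixed six-decimal formatting, so reruns with the same seed are
#' byte-identical.
#'
#' @param psa A `psa_result` (or a CEAC data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(psa, path) {
  curve <- if (inherits(psa, "psa_result")) psa$ceac else psa
  lines <- c("wtp,probability",
             sprintf("%.2f,%.6f", curve$wtp, curve$probability))
  writeLines(lines, path)
  invisible(path)
}
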