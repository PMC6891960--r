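#' Published aggregate tables used for calibration
#'
#' Loads the packaged transcription of the published inputs (daily insulin
#' use, hypoglycaemia event rates, per-event costs) and results (annual
#' per-patient costs, QALYs, ICERs) from which the unpublished unit
#' parameters are back-derived.
#'
#' @param path Path to a YAML file with the same structure; defaults to the
#'   packaged transcription.
#' @return A list of class `published_tables`.
#' @export
published_tables <- function(path = system.file("extdata",
                                                "published_tables.yaml",
                                                package = "insulinCEA")) {
  tab <- yaml::read_yaml(path)
  needed <- c("insulin_use", "event_rates", "event_cost_per_event",
              "annual_results", "flexible_dosing_utility", "wtp_threshold")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("published tables are missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(tab, class = "published_tables")
}

table_regimen <- function(tables, group) {
  u <- tables$insulin_use[[group]]
  insulin_regimen(basal_dose_glargine = u$basal_glargine,
                  basal_dose_ratio = u$basal_ratio,
                  basal_ratio_significant = u$basal_significant,
                  bolus_dose_glargine = u$bolus_glargine,
                  bolus_dose_ratio = u$bolus_ratio,
                  bolus_ratio_significant = u$bolus_significant)
}

table_rates <- function(tables, group) {
  do.call(hypo_rates, tables$event_rates[[group]]$glargine)
}

table_ratios <- function(tables, group) {
  r <- tables$event_rates[[group]]$ratio
  hypo_rate_ratios(r$daytime$value, r$nocturnal$value, r$severe$value,
                   r$daytime$significant, r$nocturnal$significant,
                   r$severe$significant)
}

#' Back-solve insulin unit prices from the published annual insulin costs
#'
#' The basal-oral group has a single-insulin arm on each side, so its two
#' insulin cost cells identify the two basal unit prices directly:
#' `price = annual cost / (dose * 365)`. For the basal-bolus groups the
#' bolus price is solved from the glargine arm's residual cost above its
#' basal component, and the group's degludec basal price from the degludec
#' arm's residual above its bolus component. Cross-group spreads (the
#' published cells are not exactly consistent with one global price set)
#' are reported in the `spread` attribute.
#'
#' @param tables A [published_tables()] object.
#' @return Named list of [unit_prices()] per group, with attribute `spread`
#'   (relative range per price across groups).
#' @export
solve_unit_prices <- function(tables) {
  days <- 365
  res <- tables$annual_results
  if (is.null(res$T2DM_BOT))
    stop("basal-oral cells are required to identify the basal prices",
         call. = FALSE)
  bot_dose_gla <- tables$insulin_use$T2DM_BOT$basal_glargine
  bot_dose_deg <- degludec_doses(table_regimen(tables, "T2DM_BOT"))$basal
  p_gla <- res$T2DM_BOT$insulin$glargine / (bot_dose_gla * days)
  p_deg_bot <- res$T2DM_BOT$insulin$degludec / (bot_dose_deg * days)
  if (p_gla <= 0 || p_deg_bot <= 0)
    stop("non-positive solved basal price: inconsistent insulin cells",
         call. = FALSE)

  prices <- list()
  for (group in patient_groups()) {
    reg <- table_regimen(tables, group)
    if (!has_bolus(reg)) {
      prices[[group]] <- unit_prices(p_gla, p_deg_bot)
      next
    }
    cells <- res[[group]]$insulin
    basal_gla_cost <- reg$basal_dose_glargine * p_gla * days
    p_bol <- (cells$glargine - basal_gla_cost) / (reg$bolus_dose_glargine * days)
    deg <- degludec_doses(reg)
    p_deg <- (cells$degludec - deg$bolus * p_bol * days) / (deg$basal * days)
    if (p_bol <= 0 || p_deg <= 0)
      stop("non-positive solved price: inconsistent insulin cells",
           call. = FALSE)
    prices[[group]] <- unit_prices(p_gla, p_deg, p_bol)
  }
  basal_deg <- vapply(prices, function(p) p$price_basal_degludec, numeric(1))
  bolus <- unlist(lapply(prices, function(p) p$price_bolus))
  attr(prices, "spread") <- c(price_basal_glargine = 0,
                              price_basal_degludec = rel_range(basal_deg),
                              price_bolus = rel_range(bolus))
  prices
}

#' Back-solve effective per-event hypoglycaemia costs
#'
#' Per group and category, the per-event cost is the published glargine-arm
#' annual cost cell divided by the glargine event rate. The degludec arm
#' provides an independent solve (cell divided by the unrounded degludec
#' rate) used as a within-group consistency check; the relative discrepancy
#' per category is returned in the `discrepancy` attribute.
#'
#' @param tables A [published_tables()] object.
#' @param max_discrepancy Warn when an across-arm discrepancy exceeds this
#'   relative tolerance (default 0.002).
#' @return Named list of [event_costs()] per group with attributes
#'   `discrepancy` (per group/category) and `spread` (cross-group relative
#'   range per category).
#' @export
solve_event_costs <- function(tables, max_discrepancy = 0.002) {
  out <- list()
  disc <- list()
  for (group in patient_groups()) {
    gla_rates <- table_rates(tables, group)
    deg_rates <- degludec_rates(gla_rates, table_ratios(tables, group))
    cells <- tables$annual_results[[group]]
    solve_arm <- function(arm, rates) {
      vapply(hypo_categories(), function(cat) {
        cell <- cells[[cat]][[arm]]
        rate <- rates[[cat]]
        if (rate == 0) {
          if (cell != 0)
            stop(sprintf("%s %s: zero event rate with nonzero cost cell",
                         group, cat), call. = FALSE)
          return(NA_real_)  # unidentifiable
        }
        cell / rate
      }, numeric(1))
    }
    c_gla <- solve_arm("glargine", gla_rates)
    c_deg <- solve_arm("degludec", deg_rates)
    disc[[group]] <- abs(c_deg - c_gla) / c_gla
    if (any(disc[[group]] > max_discrepancy, na.rm = TRUE))
      warning(sprintf("%s: per-event cost differs across arms by more than %.2f%%",
                      group, 100 * max_discrepancy), call. = FALSE)
    missing_cat <- names(c_gla)[is.na(c_gla)]
    c_fill <- ifelse(is.na(c_gla), 0, c_gla)  # zero-rate, zero-cost category
    out[[group]] <- event_costs(c_fill[["daytime"]], c_fill[["nocturnal"]],
                                c_fill[["severe"]])
    attr(out[[group]], "missing") <- missing_cat
  }
  per_cat <- sapply(hypo_categories(), function(cat)
    vapply(out, function(ec) ec$per_event[[cat]], numeric(1)))
  attr(out, "discrepancy") <- disc
  attr(out, "spread") <- apply(per_cat, 2, rel_range)
  out
}

#' Back-solve per-event disutilities from the published QALY differences
#'
#' The three published QALY increments form a triangular linear system in
#' the three disutilities, because the groups differ in which event
#' categories show a treatment effect: the type 1 group has only a
#' nocturnal rate difference (identifying the nocturnal disutility), the
#' type 2 basal-bolus group adds a daytime difference, and the basal-oral
#' group adds a severe difference. Each increment satisfies
#' `dQALY = flexible_utility + sum(rate difference * disutility)`; the
#' mortality pathway is absorbed into the severe disutility.
#'
#' @param tables A [published_tables()] object.
#' @param flexible_utility Flexible-dosing utility gain (default the
#'   published 0.006).
#' @return Named numeric vector of disutilities (daytime, nocturnal,
#'   severe), utility loss per event.
#' @export
solve_disutilities <- function(tables,
                               flexible_utility = tables$flexible_dosing_utility) {
  deltas <- lapply(patient_groups(), function(group) {
    gla <- table_rates(tables, group)
    deg <- degludec_rates(gla, table_ratios(tables, group))
    list(rate = unclass(gla) - unclass(deg),
         dq = tables$annual_results[[group]]$qalys$incremental)
  })
  names(deltas) <- patient_groups()

  d <- c(daytime = 0, nocturnal = 0, severe = 0)
  t1 <- deltas$T1DM_BB
  d[["nocturnal"]] <- (t1$dq - flexible_utility) / t1$rate[["nocturnal"]]
  bb <- deltas$T2DM_BB
  d[["daytime"]] <- (bb$dq - flexible_utility -
                       bb$rate[["nocturnal"]] * d[["nocturnal"]]) /
    bb$rate[["daytime"]]
  bot <- deltas$T2DM_BOT
  d[["severe"]] <- (bot$dq - flexible_utility -
                      bot$rate[["nocturnal"]] * d[["nocturnal"]] -
                      bot$rate[["daytime"]] * d[["daytime"]]) /
    bot$rate[["severe"]]
  if (any(d < 0))
    stop("negative solved disutility: inconsistent flexible-utility assumption",
         call. = FALSE)
  if (any(d >= 0.15))
    warning("solved disutility outside the plausible range (0, 0.15)",
            call. = FALSE)
  d
}

#' Back-solve baseline utilities from the published arm QALYs
#'
#' The glargine arm carries no flexible-dosing utility, so its baseline is
#' the published arm QALYs plus the event disutility burden. The degludec
#' arm (published QALYs plus its burden minus the flexible-dosing utility)
#' is used as a cross-check; a relative disagreement above 0.2% or a
#' baseline outside (0, 1] is flagged in the attributes rather than raised.
#'
#' @param tables A [published_tables()] object.
#' @param disutilities Named disutility vector from [solve_disutilities()].
#' @param flexible_utility Flexible-dosing utility gain.
#' @return Named numeric vector of baseline utilities per group, with
#'   attributes `arm_disagreement` and `valid`.
#' @export
solve_baseline_utilities <- function(tables, disutilities,
                                     flexible_utility = tables$flexible_dosing_utility) {
  base <- disagree <- numeric(0)
  for (group in patient_groups()) {
    gla_rates <- table_rates(tables, group)
    deg_rates <- degludec_rates(gla_rates, table_ratios(tables, group))
    q <- tables$annual_results[[group]]$qalys
    b_gla <- q$glargine + sum(unclass(gla_rates) * disutilities)
    b_deg <- q$degludec + sum(unclass(deg_rates) * disutilities) -
      flexible_utility
    base[[group]] <- b_gla
    disagree[[group]] <- abs(b_deg - b_gla) / b_gla
  }
  attr(base, "arm_disagreement") <- disagree
  attr(base, "valid") <- base > 0 & base <= 1
  base
}

#' Price-year adjustment factor implied by the published per-event costs
#'
#' Category-wise ratio of the later-year to earlier-year per-event costs,
#' with the mean and relative spread across categories.
#'
#' @param tables A [published_tables()] object.
#' @return List with `per_category`, `mean` and `spread`.
#' @export
solve_inflation_factor <- function(tables) {
  c14 <- unlist(tables$event_cost_per_event$cost_2014)[hypo_categories()]
  c18 <- unlist(tables$event_cost_per_event$cost_2018)[hypo_categories()]
  ratio <- c18 / c14
  list(per_category = ratio, mean = mean(ratio), spread = rel_range(ratio))
}

#' Calibrate the full parameter set from the published tables
#'
#' Runs all linear back-solves ([solve_unit_prices()],
#' [solve_event_costs()], [solve_disutilities()],
#' [solve_baseline_utilities()], [solve_inflation_factor()]), assembles one
#' complete [model_parameters()] set per patient group, re-runs the forward
#' model, and reports the residual against every published annual cost and
#' QALY cell and ICER. Calibration is per patient group because the
#' published cells are not jointly consistent with a single global
#' parameter set; the cross-group spreads quantify that inconsistency.
#'
#' @param tables A [published_tables()] object.
#' @param flexible_utility Flexible-dosing utility gain used in the QALY
#'   solves (default the published 0.006).
#' @return An object of class `calibration_report`: `parameters` (per-group
#'   `model_parameters`), `residuals` (data frame of published vs modelled
#'   cells with relative errors), `icers`, `spreads`, `disutilities`,
#'   `baseline_utilities`, `inflation`, `max_residual`.
#' @export
calibrate <- function(tables = published_tables(),
                      flexible_utility = tables$flexible_dosing_utility) {
  prices <- solve_unit_prices(tables)
  costs <- solve_event_costs(tables)
  disutil <- solve_disutilities(tables, flexible_utility)
  baseline <- solve_baseline_utilities(tables, disutil, flexible_utility)
  inflation <- solve_inflation_factor(tables)

  params <- list()
  for (group in patient_groups()) {
    ec <- costs[[group]]$per_event
    params[[group]] <- model_parameters(
      group = group,
      regimen = table_regimen(tables, group),
      prices = prices[[group]],
      glargine_rates = table_rates(tables, group),
      rate_ratios = table_ratios(tables, group),
      event_costs = event_costs(ec[["daytime"]], ec[["nocturnal"]],
                                ec[["severe"]]),
      utilities = utility_inputs(
        baseline_utility = baseline[[group]],
        disutility_daytime = disutil[["daytime"]],
        disutility_nocturnal = disutil[["nocturnal"]],
        disutility_severe = disutil[["severe"]],
        flexible_dosing_utility = flexible_utility,
        mortality_risk_severe = tables$mortality_risk_severe %||% 0.0112))
  }

  residuals <- do.call(rbind, lapply(patient_groups(), function(group) {
    ev <- evaluate_group(params[[group]])
    cells <- tables$annual_results[[group]]
    rows <- lapply(c("degludec", "glargine"), function(arm) {
      out <- ev[[arm]]
      modelled <- c(insulin = out$insulin_cost,
                    daytime = out$hypo_cost[["daytime"]],
                    nocturnal = out$hypo_cost[["nocturnal"]],
                    severe = out$hypo_cost[["severe"]],
                    hypo_total = sum(out$hypo_cost),
                    total = out$total_cost,
                    qalys = out$qalys)
      published <- vapply(names(modelled), function(row) cells[[row]][[arm]],
                          numeric(1))
      data.frame(group = group, row = names(modelled), arm = arm,
                 published = published, modelled = unname(modelled),
                 rel_error = rel_err(unname(modelled), published),
                 row.names = NULL)
    })
    icer_row <- data.frame(group = group, row = "icer", arm = "incremental",
                           published = cells$icer,
                           modelled = ev$comparison$icer,
                           rel_error = rel_err(ev$comparison$icer, cells$icer),
                           row.names = NULL)
    rbind(rows[[1L]], rows[[2L]], icer_row)
  }))

  icers <- residuals[residuals$row == "icer",
                     c("group", "published", "modelled", "rel_error")]
  cell_res <- residuals[residuals$row != "icer", ]

  structure(list(parameters = params,
                 residuals = residuals,
                 icers = icers,
                 spreads = list(prices = attr(prices, "spread"),
                                event_costs = attr(costs, "spread")),
                 event_cost_arm_discrepancy = attr(costs, "discrepancy"),
                 disutilities = disutil,
                 baseline_utilities = baseline,
                 inflation = inflation,
                 flexible_utility = flexible_utility,
                 wtp_threshold = tables$wtp_threshold,
                 max_residual = max(cell_res$rel_error)),
            class = "calibration_report")
}

#' Calibrated model parameters for one patient group
#'
#' Convenience wrapper: runs [calibrate()] and returns the complete
#' parameter set for one group.
#'
#' @param group One of [patient_groups()].
#' @param tables A [published_tables()] object.
#' @return A `model_parameters` object.
#' @export
calibrated_parameters <- function(group = patient_groups(),
                                  tables = published_tables()) {
  group <- match.arg(group)
  calibrate(tables)$parameters[[group]]
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration from published aggregate tables\n")
  cat(sprintf("  max cost/QALY cell residual: %.4f%%\n", 100 * x$max_residual))
  cat("  ICERs (BGN/QALY):\n")
  for (i in seq_len(nrow(x$icers)))
    cat(sprintf("    %-8s published %8.2f  modelled %8.2f  (%.3f%%)\n",
                x$icers$group[i], x$icers$published[i], x$icers$modelled[i],
                100 * x$icers$rel_error[i]))
  cat(sprintf("  disutilities/event: daytime %.5f, nocturnal %.5f, severe %.5f\n",
              x$disutilities[["daytime"]], x$disutilities[["nocturnal"]],
              x$disutilities[["severe"]]))
  cat(sprintf("  price-year factor: %.5f (spread %.3f%%)\n",
              x$inflation$mean, 100 * x$inflation$spread))
  invisible(x)
}

#' Write a calibration report to disk
#'
#' Emits the machine-readable report (JSON), the residual table (CSV) and
#' one reloadable YAML parameter configuration per patient group, so the
#' forward model never hard-codes derived numbers.
#'
#' @param report A `calibration_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_calibration <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  json_path <- file.path(dir, "calibration_report.json")
  payload <- list(
    max_residual = report$max_residual,
    icers = report$icers,
    spreads = report$spreads,
    disutilities = as.list(report$disutilities),
    baseline_utilities = as.list(unclass(report$baseline_utilities)),
    inflation = report$inflation,
    flexible_utility = report$flexible_utility,
    wtp_threshold = report$wtp_threshold)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, json_path)
  csv_path <- file.path(dir, "calibration_residuals.csv")
  utils::write.csv(report$residuals, csv_path, row.names = FALSE)
  files <- c(files, csv_path)
  for (group in names(report$parameters)) {
    p <- file.path(dir, sprintf("parameters_%s.yaml", tolower(group)))
    write_parameters(report$parameters[[group]], p)
    files <- c(files, p)
  }
  invisible(files)
}
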