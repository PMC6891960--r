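#' Tabulate a group evaluation in the published row structure
#'
#' One row per cost component (insulin; the three hypoglycaemia
#' categories and their subtotal), total costs, QALYs and the ICER, with
#' degludec, glargine U100 and incremental columns. Values are carried at
#' full precision; rounding to the published two (costs) / four (QALYs)
#' decimals happens only in the writers.
#'
#' @param evaluation A [evaluate_group()] result, or a
#'   [model_parameters()] object (evaluated first).
#' @return Data frame with columns `row`, `degludec`, `glargine`,
#'   `incremental`.
#' @export
group_report <- function(evaluation) {
  if (inherits(evaluation, "model_parameters"))
    evaluation <- evaluate_group(evaluation)
  stopifnot(inherits(evaluation, "group_evaluation"))
  deg <- evaluation$degludec; gla <- evaluation$glargine
  cmp <- evaluation$comparison
  col <- function(out) c(out$insulin_cost,
                         sum(out$hypo_cost),
                         out$hypo_cost[["daytime"]],
                         out$hypo_cost[["nocturnal"]],
                         out$hypo_cost[["severe"]],
                         out$total_cost,
                         out$qalys)
  d <- col(deg); g <- col(gla)
  rows <- c("Insulin", "Hypoglycaemia events", "Non-severe daytime events",
            "Non-severe nocturnal events", "Severe events", "Total costs",
            "QALYs")
  out <- data.frame(row = c(rows, "ICER (cost/QALY)"),
                    degludec = c(d, NA),
                    glargine = c(g, NA),
                    incremental = c(d - g, cmp$icer),
                    row.names = NULL)
  attr(out, "dominance") <- cmp$dominance
  out
}

#' Write a group evaluation report (CSV and JSON)
#'
#' The CSV mirrors the published table layout (costs rounded to 2
#' decimals, QALYs to 4); the JSON carries the full-precision values plus
#' the dominance class and net monetary benefit at the threshold.
#'
#' @param evaluation A `group_evaluation` or `model_parameters`.
#' @param dir Output directory (created if needed).
#' @param wtp Willingness-to-pay threshold for the NMB summary.
#' @return Character vector of files written, invisibly.
#' @export
write_group_report <- function(evaluation, dir, wtp = 39619) {
  if (inherits(evaluation, "model_parameters"))
    evaluation <- evaluate_group(evaluation)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  group <- evaluation$params$group
  tab <- group_report(evaluation)
  rounded <- tab
  money <- tab$row != "QALYs"
  for (colnm in c("degludec", "glargine", "incremental")) {
    rounded[[colnm]][money] <- round(tab[[colnm]][money], 2)
    rounded[[colnm]][!money] <- round(tab[[colnm]][!money], 4)
  }
  csv_path <- file.path(dir, sprintf("results_%s.csv", tolower(group)))
  utils::write.csv(rounded, csv_path, row.names = FALSE, na = "")
  cmp <- evaluation$comparison
  json_path <- file.path(dir, sprintf("results_%s.json", tolower(group)))
  jsonlite::write_json(
    list(group = group,
         table = tab,
         delta_cost = cmp$delta_cost,
         delta_qalys = cmp$delta_qalys,
         icer = cmp$icer,
         dominance = cmp$dominance,
         wtp = wtp,
         net_monetary_benefit = net_monetary_benefit(cmp, wtp)),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv_path, json_path))
}

#' Write a run manifest
#'
#' Records the command, inputs, seed, package version, timestamp and the
#' complete output file list of an analysis run. Written last, so the
#' presence of a manifest implies the listed outputs are complete.
#'
#' @param dir Directory the manifest describes.
#' @param command Short name of the analysis step.
#' @param inputs Character vector of input descriptions/paths.
#' @param outputs Character vector of files written by the step.
#' @param seed Seed used (or `NA` for deterministic steps).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, inputs = character(0),
                               outputs = character(0), seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(
    list(command = command,
         inputs = inputs,
         seed = seed,
         package_version = as.character(utils::packageVersion("insulinCEA")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = basename(outputs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
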