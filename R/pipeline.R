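#' Run the full benefit-risk assessment pipeline
#'
#' Chains the stages on file inputs: Delphi screening (when a panel is
#' given), random-effects pooling (when trial-level data are given, else a
#' pre-pooled table), linear partial-value scoring and aggregation, and
#' Monte Carlo uncertainty propagation. Stages without inputs are skipped
#' and marked so in the report. All settings and the seed are echoed for
#' reproducibility; the report is returned and, when `out_json` is given,
#' written as JSON.
#'
#' @param tree_path path to the criteria-tree YAML (required).
#' @param panel_path optional CSV of raw panel responses (see
#'   [read_panel()]).
#' @param trials_path optional CSV of trial-level rows with a
#'   `criterion_id` column (see [pool_by_criterion()]).
#' @param pooled_path optional CSV of pre-pooled estimates (see
#'   [read_pooled_table()]); ignored when `trials_path` is given.
#' @param pooled_group group to select from `pooled_path`.
#' @param rule [screening_rule()] for the Delphi stage.
#' @param config [mc_config()] for the Monte Carlo stage.
#' @param out_json optional path for the JSON report.
#' @return the report as a list: settings, per-stage results (or a
#'   `"skipped"` marker), deterministic BRA result, and Monte Carlo
#'   summary.
#' @export
run_pipeline <- function(tree_path, panel_path = NULL, trials_path = NULL,
                         pooled_path = NULL, pooled_group = NULL,
                         rule = screening_rule(), config = mc_config(),
                         out_json = NULL) {
  tree <- read_criteria_tree(tree_path)
  report <- list(settings = list(
    tree_path = tree_path, pooled_group = pooled_group,
    iterations = config$iterations, seed = config$seed,
    clamp = config$clamp, mode = config$mode))

  if (!is.null(panel_path)) {
    panel <- read_panel(panel_path)
    stats <- panel_stats(panel)
    retained <- screen_criteria(stats, rule)
    report$delphi <- list(retained = as.character(retained),
                          stats = stats,
                          rule = unclass(rule)[c("min_mean",
                                                 "min_max_score_freq",
                                                 "max_cv")])
  } else {
    report$delphi <- "skipped (no panel input)"
  }

  estimates <- NULL
  if (!is.null(trials_path)) {
    trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
    estimates <- pool_by_criterion(trials)
    report$pooling <- pooled_table(estimates)
  } else if (!is.null(pooled_path)) {
    estimates <- read_pooled_table(pooled_path, group = pooled_group)
    report$pooling <- "loaded pre-pooled estimates"
  } else {
    report$pooling <- "skipped (no trial or pooled input)"
  }

  if (!is.null(estimates)) {
    res <- bra_value(tree, estimates, clamp = config$clamp,
                     mode = config$mode)
    ct <- contribution_table(res, tree)
    mc <- simulate_bra(tree, estimates, config)
    report$value_model <- list(
      benefit_value = res$benefit_value, risk_value = res$risk_value,
      overall = res$overall, overall_rounded = res$overall_rounded,
      scores = res$scores, contributions = ct)
    report$monte_carlo <- list(mean = mc$mean, ci_low = mc$ci_low,
                               ci_high = mc$ci_high,
                               iterations = mc$iterations, seed = mc$seed)
  } else {
    report$value_model <- "skipped (no estimates)"
    report$monte_carlo <- "skipped (no estimates)"
  }

  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, force = TRUE)
  }
  invisible(report)
}
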