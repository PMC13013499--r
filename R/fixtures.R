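#' Bundled Fuzi-RA case-study inputs
#'
#' The package ships the published summary inputs of its worked case —
#' Fuzi-containing decoctions versus standard treatment in rheumatoid
#' arthritis — as plain-text fixtures: the Delphi panel summary statistics
#' for all candidate criteria, the criteria tree with weights and anchors,
#' the dose-group pooled estimates, and the treatment-duration contribution
#' table.
#'
#' @name fuzi_fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "bramcda")
  if (p == "") bra_abort(sprintf("fixture '%s' not found", file))
  p
}

#' Delphi panel summary statistics for the Fuzi-RA candidate criteria
#'
#' Mean, full-score frequency and coefficient of variation of the 22-expert
#' panel's importance and feasibility ratings for 17 benefit and 9 risk
#' candidate criteria, in the [panel_stats()] row format (plus a `branch`
#' column).
#'
#' @return data frame.
#' @export
fuzi_panel_stats <- function() {
  utils::read.csv(fixture_path("table4_panel_stats.csv"),
                  stringsAsFactors = FALSE)
}

#' The Fuzi-RA criteria tree
#'
#' Ten criteria (5 benefit, 5 risk), percentage weights (benefit branch
#' 49%, risk branch 51%), and the best/worst effect anchors.
#'
#' @return a [criteria_tree()].
#' @export
fuzi_tree <- function() {
  read_criteria_tree(fixture_path("fuzi_ra_tree.yaml"))
}

#' Dose-group pooled estimates for the Fuzi-RA case
#'
#' Random-effects pooled effects and 95% CIs per criterion for the two
#' dose groups (`"low_dose"` = 3-15 g, `"high_dose"` = above 15 g).
#' Criteria with no estimable evidence (no events observed in any trial)
#' are `NULL`.
#'
#' @param group `"low_dose"` or `"high_dose"`.
#' @return named list of [pooled_estimate()] objects (or `NULL`).
#' @export
fuzi_pooled <- function(group = c("low_dose", "high_dose")) {
  group <- match.arg(group)
  read_pooled_table(fixture_path("table6_pooled.csv"), group = group)
}

#' Treatment-duration contribution table for the Fuzi-RA case
#'
#' Per-criterion weighted contributions (weight x score / 100) for the
#' three treatment-duration groups; `NA` marks criteria with no estimable
#' evidence in that group.
#'
#' @param group one of `"within_2_months"`, `"months_2_to_3"`,
#'   `"over_3_months"`; `NULL` returns all groups.
#' @return data frame for [combine_contributions()].
#' @export
fuzi_contributions <- function(group = NULL) {
  d <- utils::read.csv(fixture_path("table7_contributions.csv"),
                       stringsAsFactors = FALSE)
  if (!is.null(group)) {
    stopifnot(group %in% d$group)
    d <- d[d$group == group, , drop = FALSE]
  }
  d
}

#' The Delphi screening rule of the Fuzi-RA case
#'
#' Mean >= 3.5, full-score frequency >= 0.2, CV < 0.25 in both dimensions,
#' with the liver and kidney adverse-event criteria merged after screening.
#'
#' @return a [screening_rule()].
#' @export
fuzi_screening_rule <- function() {
  screening_rule(min_mean = 3.5, min_max_score_freq = 0.2, max_cv = 0.25,
                 merge_map = list(liver_kidney_adr = c("liver_adr",
                                                       "kidney_adr")))
}
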