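#' Delphi panel statistics and criterion screening
#'
#' One round of a Delphi survey scores every candidate criterion on two
#' 5-point Likert dimensions (importance and feasibility). Criteria are kept
#' when the panel rates them highly and agrees: the arithmetic mean score,
#' the frequency of the maximum (full) score, and the coefficient of
#' variation must each pass a threshold in both dimensions. Retained
#' criteria are then weighted from the experts' importance rankings by the
#' percentage weighting method.
#'
#' @name delphi
NULL

#' Summarise panel scores for one criterion and dimension
#'
#' Computes the arithmetic mean, the frequency of the maximum score, and the
#' coefficient of variation (population SD divided by the mean) of the
#' Likert scores one criterion received on one dimension.
#'
#' @param panel a panel dataset as returned by [read_panel()] or
#'   [gen_expert_panel()]: a data frame with columns `expert_id`,
#'   `criterion_id`, `dimension` (`"importance"` or `"feasibility"`) and
#'   integer `score` in 1..5.
#' @param criterion_id criterion to summarise.
#' @param dimension `"importance"` or `"feasibility"`.
#' @param max_score the Likert ceiling counted as a "full score" (default 5).
#' @param sd_type `"population"` (divisor m, the default) or `"sample"`
#'   (divisor m - 1) for the SD entering the coefficient of variation.
#' @return a one-row data frame with columns `criterion_id`, `dimension`,
#'   `mean`, `max_score_freq`, `cv`, `n_raters`.
#' @export
#' @examples
#' panel <- data.frame(expert_id = 1:4, criterion_id = "esr",
#'                     dimension = "importance", score = c(5, 5, 4, 3))
#' compute_criterion_stats(panel, "esr", "importance")
compute_criterion_stats <- function(panel, criterion_id, dimension,
                                    max_score = 5,
                                    sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  validate_panel(panel)
  s <- panel$score[panel$criterion_id == criterion_id &
                   panel$dimension == dimension]
  if (length(s) == 0L) {
    bra_abort(sprintf("no responses for criterion '%s', dimension '%s'",
                      criterion_id, dimension), "bramcda_empty_criterion")
  }
  m <- length(s)
  mu <- mean(s)
  dev <- if (sd_type == "population") {
    sqrt(sum((s - mu)^2) / m)
  } else {
    stats::sd(s)
  }
  data.frame(criterion_id = criterion_id, dimension = dimension,
             mean = mu, max_score_freq = sum(s == max_score) / m,
             cv = dev / mu, n_raters = m, stringsAsFactors = FALSE)
}

#' Summarise every criterion/dimension pair of a panel
#'
#' @inheritParams compute_criterion_stats
#' @return a data frame with one row per (criterion, dimension), the
#'   row format of [compute_criterion_stats()].
#' @export
panel_stats <- function(panel, max_score = 5,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  validate_panel(panel)
  keys <- unique(panel[, c("criterion_id", "dimension")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    compute_criterion_stats(panel, keys$criterion_id[i], keys$dimension[i],
                            max_score = max_score, sd_type = sd_type)
  })
  do.call(rbind, out)
}

validate_panel <- function(panel) {
  need <- c("expert_id", "criterion_id", "dimension", "score")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    bra_abort(paste("panel must be a data frame with columns",
                    paste(need, collapse = ", ")))
  }
  if (!all(panel$score %in% 1:5)) {
    bra_abort("Likert scores must be integers in 1..5")
  }
  if (!all(panel$dimension %in% c("importance", "feasibility"))) {
    bra_abort("dimension must be 'importance' or 'feasibility'")
  }
  dup <- duplicated(panel[, c("expert_id", "criterion_id", "dimension")])
  if (any(dup)) {
    bra_abort("at most one score per (expert, criterion, dimension)")
  }
  invisible(panel)
}

#' Screening rule for Delphi criterion selection
#'
#' Thresholds a criterion must pass, in both the importance and the
#' feasibility dimension, to be retained: mean score at least `min_mean`,
#' full-score frequency at least `min_max_score_freq`, coefficient of
#' variation strictly below `max_cv`. An optional `merge_map` collapses
#' groups of retained criteria (e.g. liver and kidney damage) into a single
#' merged criterion.
#'
#' @param min_mean minimum mean Likert score (default 3.5).
#' @param min_max_score_freq minimum frequency of the full score (default 0.2).
#' @param max_cv exclusive upper bound on the coefficient of variation
#'   (default 0.25).
#' @param merge_map named list: each element is a character vector of
#'   criterion ids to merge, the element's name is the merged id.
#' @return an object of class `screening_rule`.
#' @export
screening_rule <- function(min_mean = 3.5, min_max_score_freq = 0.2,
                           max_cv = 0.25, merge_map = list()) {
  assert_number(min_mean, "min_mean")
  assert_number(min_max_score_freq, "min_max_score_freq")
  assert_number(max_cv, "max_cv")
  if (min_mean <= 0 || max_cv <= 0) bra_abort("thresholds must be positive")
  structure(list(min_mean = min_mean,
                 min_max_score_freq = min_max_score_freq,
                 max_cv = max_cv, merge_map = merge_map),
            class = "screening_rule")
}

#' Screen criteria by panel consensus thresholds
#'
#' A criterion is retained iff its mean, full-score frequency and
#' coefficient of variation pass the rule's thresholds in *both* the
#' importance and the feasibility dimension. Retained criteria listed
#' together in the rule's `merge_map` are collapsed into one merged id
#' (stats of the first group member are carried). Output is ordered by
#' descending importance mean, ties broken alphabetically by id.
#'
#' @param stats a data frame of per-criterion, per-dimension summaries in
#'   the format of [panel_stats()] (columns `criterion_id`, `dimension`,
#'   `mean`, `max_score_freq`, `cv`).
#' @param rule a [screening_rule()].
#' @return a character vector of retained (possibly merged) criterion ids,
#'   with attribute `"report"` holding a data frame of per-criterion
#'   decisions.
#' @export
screen_criteria <- function(stats, rule = screening_rule()) {
  stopifnot(inherits(rule, "screening_rule"))
  ids <- unique(stats$criterion_id)
  imp <- stats[stats$dimension == "importance", , drop = FALSE]
  fea <- stats[stats$dimension == "feasibility", , drop = FALSE]
  missing_dim <- ids[!(ids %in% imp$criterion_id) | !(ids %in% fea$criterion_id)]
  if (length(missing_dim) > 0L) {
    bra_abort(sprintf("criterion missing a dimension: %s",
                      paste(missing_dim, collapse = ", ")))
  }
  passes <- function(d, id) {
    r <- d[d$criterion_id == id, ][1L, ]
    r$mean >= rule$min_mean &&
      r$max_score_freq >= rule$min_max_score_freq &&
      r$cv < rule$max_cv
  }
  keep <- vapply(ids, function(id) passes(imp, id) && passes(fea, id),
                 logical(1))
  report <- data.frame(criterion_id = ids, retained = keep,
                       importance_mean = imp$mean[match(ids, imp$criterion_id)],
                       stringsAsFactors = FALSE)
  retained <- report[report$retained, , drop = FALSE]
  # collapse merge groups among the retained set
  for (merged in names(rule$merge_map)) {
    members <- intersect(rule$merge_map[[merged]], retained$criterion_id)
    if (length(members) > 0L) {
      first <- match(members[1L], retained$criterion_id)
      retained$criterion_id[first] <- merged
      retained <- retained[!(retained$criterion_id %in% members), , drop = FALSE]
    }
  }
  ord <- order(-retained$importance_mean, retained$criterion_id)
  out <- retained$criterion_id[ord]
  attr(out, "report") <- report
  out
}

#' Percentage weights from rank tallies
#'
#' Converts the panel's importance rankings into percentage weights: with
#' rank values w (default 10 down to 1 for 10 criteria) and N_ij experts
#' placing criterion j at rank i, the weight of criterion j is
#' sum_i(w_i N_ij) / (N sum_i w_i), N the number of valid questionnaires.
#' When every expert ranks all criteria exactly once, the weights sum to 1.
#'
#' @param tallies a data frame with columns `criterion_id`, `rank_position`
#'   (1 = top), and `count` (number of experts assigning that position).
#' @param n_valid number of valid questionnaires (N).
#' @param rank_values descending scores attached to rank positions; defaults
#'   to `k..1` where `k` is the number of distinct criteria.
#' @return a named numeric vector of weight fractions, one per criterion.
#' @export
#' @examples
#' t <- data.frame(criterion_id = letters[1:3], rank_position = 1:3, count = 1)
#' percentage_weights(t, n_valid = 1, rank_values = 3:1)
percentage_weights <- function(tallies, n_valid, rank_values = NULL) {
  stopifnot(is.data.frame(tallies),
            all(c("criterion_id", "rank_position", "count") %in% names(tallies)))
  if (n_valid <= 0) bra_abort("n_valid must be positive")
  if (any(tallies$count < 0) || any(tallies$count != floor(tallies$count))) {
    bra_abort("tally counts must be non-negative integers")
  }
  ids <- unique(tallies$criterion_id)
  if (is.null(rank_values)) rank_values <- rev(seq_along(ids))
  per_rank <- tapply(tallies$count, tallies$rank_position, sum)
  if (any(per_rank > n_valid)) {
    bra_abort("tally counts exceed n_valid for some rank position")
  }
  denom <- n_valid * sum(rank_values)
  w <- vapply(ids, function(id) {
    tj <- tallies[tallies$criterion_id == id, , drop = FALSE]
    if (any(tj$rank_position > length(rank_values))) {
      bra_abort("rank_position beyond the rank_values ladder")
    }
    sum(rank_values[tj$rank_position] * tj$count) / denom
  }, numeric(1))
  names(w) <- ids
  w
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m experts each ranking n items, with the standard tie
#' correction. W is 1 for identical rankings and 0 when rank sums are all
#' equal. The chi-square approximation m(n-1)W with n-1 degrees of freedom
#' is attached for significance testing.
#'
#' @param rankings numeric matrix, experts in rows, items in columns; each
#'   row holds the ranks (1 = most important) that expert gave the items.
#'   Tied ranks are expressed as mid-ranks, as [base::rank()] produces.
#' @return a list with elements `w`, `chisq`, `df`, `p_value`, `n_experts`,
#'   `n_items`.
#' @export
kendall_w <- function(rankings) {
  rankings <- as.matrix(rankings)
  m <- nrow(rankings); n <- ncol(rankings)
  if (m < 2L) bra_abort("kendall_w needs at least two experts")
  if (n < 2L) bra_abort("kendall_w needs at least two items")
  rank_sums <- colSums(rankings)
  s <- sum((rank_sums - mean(rank_sums))^2)
  # tie correction: sum over experts of (t^3 - t) per tied group
  tie_term <- sum(apply(rankings, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) / 12 - m * tie_term / 12
  w <- if (denom <= 0) 0 else s / denom
  chisq <- m * (n - 1) * w
  list(w = w, chisq = chisq, df = n - 1L,
       p_value = stats::pchisq(chisq, df = n - 1L, lower.tail = FALSE),
       n_experts = m, n_items = n)
}

#' Expert authority coefficient
#'
#' Conventional Delphi credibility index Cr = (Ca + Cs) / 2, where Ca is
#' the mean judgment-basis self-rating and Cs the mean familiarity
#' self-rating, both rescaled from the 1..5 quantification to (0, 1].
#'
#' @param self_assessments data frame with columns `expert_id`,
#'   `judgment_basis`, `familiarity`, both integer 1..5.
#' @return a single number in (0, 1].
#' @export
#' @examples
#' sa <- data.frame(expert_id = 1:2, judgment_basis = c(4, 4), familiarity = c(3, 3))
#' authority_coefficient(sa)  # 0.7
authority_coefficient <- function(self_assessments) {
  stopifnot(is.data.frame(self_assessments))
  if (nrow(self_assessments) == 0L) {
    bra_abort("self_assessments is empty")
  }
  if (!all(self_assessments$judgment_basis %in% 1:5) ||
      !all(self_assessments$familiarity %in% 1:5)) {
    bra_abort("self-assessment scores must be integers in 1..5")
  }
  ca <- mean(self_assessments$judgment_basis) / 5
  cs <- mean(self_assessments$familiarity) / 5
  (ca + cs) / 2
}

#' Read a Delphi panel from CSV
#'
#' @param path CSV with columns `expert_id`, `criterion_id`, `dimension`,
#'   `score`.
#' @return a validated panel data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}
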