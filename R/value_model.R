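#' Linear partial-value scoring and weighted aggregation
#'
#' Pooled effects on heterogeneous scales (joint counts, minutes, mm/h,
#' IU/mL, risk ratios) are made commensurable by a linear partial-value
#' function anchored at a best effect (score 100) and a worst effect
#' (score 0) per criterion. Scores are aggregated through a two-branch
#' (benefit/risk) criteria tree by their percentage weights into branch
#' values and a single overall benefit-risk value on the 0-100 scale.
#'
#' @name value_model
NULL

#' Define one criterion of the value tree
#'
#' @param criterion_id identifier.
#' @param branch `"benefit"` or `"risk"`.
#' @param weight_percent percentage weight (> 0); per-branch weights sum to
#'   the branch weight.
#' @param scale effect scale, `"MD"` or `"RR"`.
#' @param anchor_best effect value mapped to score 100.
#' @param anchor_worst effect value mapped to score 0.
#' @return a `bra_criterion` list.
#' @export
criterion <- function(criterion_id, branch = c("benefit", "risk"),
                      weight_percent, scale = c("MD", "RR"),
                      anchor_best, anchor_worst) {
  branch <- match.arg(branch)
  scale <- match.arg(scale)
  assert_number(weight_percent, "weight_percent")
  if (weight_percent <= 0) bra_abort("weight_percent must be positive")
  if (anchor_best == anchor_worst) bra_abort("anchors must differ")
  structure(list(criterion_id = criterion_id, branch = branch,
                 weight_percent = weight_percent, scale = scale,
                 anchor_best = anchor_best, anchor_worst = anchor_worst),
            class = "bra_criterion")
}

#' Assemble a two-branch criteria tree
#'
#' @param criteria list of [criterion()] objects.
#' @param branch_weight_benefit,branch_weight_risk branch weights in
#'   percent; must sum to 100. Per-branch criterion weights must sum to the
#'   branch weight within `tol`.
#' @param tol rounding tolerance for the weight bookkeeping checks
#'   (default 0.5 percentage points, accommodating printed one-decimal
#'   weights).
#' @return a `criteria_tree`.
#' @export
criteria_tree <- function(criteria, branch_weight_benefit = 49,
                          branch_weight_risk = 51, tol = 0.5) {
  stopifnot(all(vapply(criteria, inherits, logical(1), "bra_criterion")))
  if (abs(branch_weight_benefit + branch_weight_risk - 100) > 1e-9) {
    bra_abort("branch weights must sum to 100")
  }
  ids <- vapply(criteria, `[[`, character(1), "criterion_id")
  if (anyDuplicated(ids)) bra_abort("duplicate criterion ids in tree")
  names(criteria) <- ids
  tree <- structure(list(criteria = criteria,
                         branch_weight_benefit = branch_weight_benefit,
                         branch_weight_risk = branch_weight_risk),
                    class = "criteria_tree")
  for (b in c("benefit", "risk")) {
    bw <- if (b == "benefit") branch_weight_benefit else branch_weight_risk
    s <- sum(tree_weights(tree, b))
    if (abs(s - bw) > tol) {
      bra_abort(sprintf("%s criterion weights sum to %.2f, not %.2f", b, s, bw))
    }
  }
  tree
}

tree_branch_ids <- function(tree, branch) {
  ids <- names(tree$criteria)
  ids[vapply(tree$criteria, function(cr) cr$branch == branch, logical(1))]
}

tree_weights <- function(tree, branch) {
  ids <- tree_branch_ids(tree, branch)
  w <- vapply(tree$criteria[ids], `[[`, numeric(1), "weight_percent")
  names(w) <- ids
  w
}

#' @export
print.criteria_tree <- function(x, ...) {
  cat(sprintf("Criteria tree: benefit %g%% / risk %g%%\n",
              x$branch_weight_benefit, x$branch_weight_risk))
  for (b in c("benefit", "risk")) {
    cat(sprintf("  %s:\n", b))
    for (id in tree_branch_ids(x, b)) {
      cr <- x$criteria[[id]]
      cat(sprintf("    %-28s w=%5.2f  %s anchors [best %g, worst %g]\n",
                  id, cr$weight_percent, cr$scale,
                  cr$anchor_best, cr$anchor_worst))
    }
  }
  invisible(x)
}

#' Read a criteria tree from YAML
#'
#' The file holds `branch_weight_benefit`, `branch_weight_risk`, and a
#' `criteria` sequence of mappings with keys `id`, `branch`,
#' `weight_percent`, `scale`, `anchor_best`, `anchor_worst`.
#'
#' @param path YAML path.
#' @return a `criteria_tree`.
#' @export
read_criteria_tree <- function(path) {
  y <- yaml::read_yaml(path)
  crits <- lapply(y$criteria, function(cr) {
    criterion(cr$id, cr$branch, cr$weight_percent, cr$scale,
              cr$anchor_best, cr$anchor_worst)
  })
  criteria_tree(crits,
                branch_weight_benefit = y$branch_weight_benefit %||% 49,
                branch_weight_risk = y$branch_weight_risk %||% 51)
}

#' Linear partial-value score of one effect
#'
#' score = 100 * (effect - anchor_worst) / (anchor_best - anchor_worst).
#' Effects beyond the anchors give scores outside 0-100 unless `clamp` is
#' set. A missing effect (`NULL` or `NA`) yields an absent score that
#' contributes zero downstream while keeping its weight in the denominator.
#'
#' @param effect pooled effect on the natural scale, or a
#'   [pooled_estimate()], or `NULL`/`NA` for an absent criterion.
#' @param criterion a [criterion()].
#' @param clamp clamp the score into \[0, 100\]? Default `FALSE`.
#' @return a one-row data frame `criterion_id`, `score`, `present`.
#' @export
#' @examples
#' cr <- criterion("tender_joints", "benefit", 11.8, "MD", -5, 0)
#' linear_score(-2.53, cr)  # 50.6
linear_score <- function(effect, criterion, clamp = FALSE) {
  stopifnot(inherits(criterion, "bra_criterion"))
  if (inherits(effect, "pooled_estimate")) effect <- effect$effect
  if (is.null(effect) || is.na(effect)) {
    return(data.frame(criterion_id = criterion$criterion_id,
                      score = NA_real_, present = FALSE,
                      stringsAsFactors = FALSE))
  }
  s <- 100 * (effect - criterion$anchor_worst) /
    (criterion$anchor_best - criterion$anchor_worst)
  if (clamp) s <- min(100, max(0, s))
  data.frame(criterion_id = criterion$criterion_id, score = s,
             present = TRUE, stringsAsFactors = FALSE)
}

#' Score every tree criterion against a set of pooled estimates
#'
#' @param tree a [criteria_tree()].
#' @param estimates named list of `pooled_estimate` objects (or `NULL`
#'   entries); names are criterion ids. Tree criteria without an entry are
#'   scored absent.
#' @inheritParams linear_score
#' @return data frame of [linear_score()] rows, one per tree criterion.
#' @export
score_estimates <- function(tree, estimates, clamp = FALSE) {
  do.call(rbind, lapply(names(tree$criteria), function(id) {
    e <- estimates[[id]]
    linear_score(if (is.null(e)) NA_real_ else e, tree$criteria[[id]],
                 clamp = clamp)
  }))
}

#' Weighted branch value
#'
#' Weighted mean of the branch's partial-value scores, with absent criteria
#' contributing zero while their weight stays in the denominator:
#' sum(w_j s_j over present j) / sum(w_j over all branch j). This is the
#' convention under which a criterion with no estimable evidence (e.g. an
#' adverse event never observed) counts as the worst score rather than
#' being renormalised away.
#'
#' @param scores data frame from [score_estimates()].
#' @param tree a [criteria_tree()].
#' @param branch `"benefit"` or `"risk"`.
#' @return the branch value (numeric scalar, nominally 0-100).
#' @export
branch_value <- function(scores, tree, branch = c("benefit", "risk")) {
  branch <- match.arg(branch)
  w <- tree_weights(tree, branch)
  if (length(w) == 0L) bra_abort(sprintf("tree has no %s criteria", branch))
  idx <- match(names(w), scores$criterion_id)
  if (anyNA(idx)) {
    bra_abort(sprintf("missing scores for: %s",
                      paste(names(w)[is.na(idx)], collapse = ", ")))
  }
  s <- scores$score[idx]
  present <- scores$present[idx]
  s[!present] <- 0
  sum(w * s) / sum(w)
}

#' Overall benefit-risk value
#'
#' Combines the two branch values. The default `weight_proportional` mode
#' weights each branch by its branch weight: overall =
#' (w_B * B + w_R * R) / 100, identical to summing all weighted criterion
#' contributions and dividing by 100. The `mean_of_branches` mode averages
#' the two branch contribution sums (each branch's sum of
#' weight * score / 100), the convention used when per-criterion
#' contributions are reported directly on the weight scale.
#'
#' @param benefit_value,risk_value branch values from [branch_value()].
#' @param tree a [criteria_tree()].
#' @param mode `"weight_proportional"` (default) or `"mean_of_branches"`.
#' @return a `bra_result` list with elements `benefit_value`, `risk_value`,
#'   `overall` (unrounded), `overall_rounded` (half-up integer), `mode`.
#' @export
overall_bra <- function(benefit_value, risk_value, tree,
                        mode = c("weight_proportional", "mean_of_branches")) {
  mode <- match.arg(mode)
  w_b <- tree$branch_weight_benefit
  w_r <- tree$branch_weight_risk
  overall <- switch(mode,
    weight_proportional = (w_b * benefit_value + w_r * risk_value) / 100,
    # branch contribution sums are branch_value * branch_weight / 100
    mean_of_branches = (w_b * benefit_value / 100 +
                        w_r * risk_value / 100) / 2)
  structure(list(benefit_value = benefit_value, risk_value = risk_value,
                 overall = overall,
                 overall_rounded = round_half_up(overall),
                 mode = mode),
            class = "bra_result")
}

#' @export
print.bra_result <- function(x, ...) {
  cat(sprintf("Benefit value %.2f | Risk value %.2f | BRA %.2f (rounds to %d, %s)\n",
              x$benefit_value, x$risk_value, x$overall,
              as.integer(x$overall_rounded), x$mode))
  invisible(x)
}

#' Full value-model computation from pooled estimates
#'
#' Scores, aggregates per branch, and combines: the deterministic pipeline
#' from a pooled-estimate table to a benefit-risk value.
#'
#' @inheritParams score_estimates
#' @inheritParams overall_bra
#' @return a `bra_result` with the score table attached as `$scores`.
#' @export
bra_value <- function(tree, estimates, clamp = FALSE,
                      mode = c("weight_proportional", "mean_of_branches")) {
  mode <- match.arg(mode)
  scores <- score_estimates(tree, estimates, clamp = clamp)
  b <- branch_value(scores, tree, "benefit")
  r <- branch_value(scores, tree, "risk")
  res <- overall_bra(b, r, tree, mode = mode)
  res$scores <- scores
  res
}

#' Per-criterion contribution table
#'
#' contribution_j = weight_percent_j * score_j / 100 on the weight scale;
#' absent criteria contribute 0 and are flagged. Branch subtotals and the
#' overall value echo the `bra_result`.
#'
#' @param result a `bra_result` from [bra_value()].
#' @param tree the [criteria_tree()] it was computed on.
#' @return data frame `criterion_id`, `branch`, `weight_percent`, `score`,
#'   `present`, `contribution`, with branch subtotals as attribute
#'   `"subtotals"`.
#' @export
contribution_table <- function(result, tree) {
  stopifnot(inherits(result, "bra_result"), !is.null(result$scores))
  sc <- result$scores
  rows <- lapply(names(tree$criteria), function(id) {
    cr <- tree$criteria[[id]]
    i <- match(id, sc$criterion_id)
    s <- if (sc$present[i]) sc$score[i] else 0
    data.frame(criterion_id = id, branch = cr$branch,
               weight_percent = cr$weight_percent,
               score = sc$score[i], present = sc$present[i],
               contribution = cr$weight_percent * s / 100,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sub <- tapply(tab$contribution, tab$branch, sum)
  attr(tab, "subtotals") <- sub
  tab
}

#' Combine reported branch contribution sums into an overall value
#'
#' For analyses reported only as per-criterion weighted contributions
#' (weight * score / 100), sums each branch and averages the two sums —
#' the `mean_of_branches` convention applied directly to contribution data.
#'
#' @param contributions data frame with columns `branch`
#'   (`"benefit"`/`"risk"`) and `contribution`; absent criteria may carry
#'   `NA` contributions, which count as zero.
#' @return list with `benefit_sum`, `risk_sum`, `overall` (unrounded) and
#'   `overall_rounded`.
#' @export
combine_contributions <- function(contributions) {
  stopifnot(all(c("branch", "contribution") %in% names(contributions)))
  x <- contributions$contribution
  x[is.na(x)] <- 0
  bs <- sum(x[contributions$branch == "benefit"])
  rs <- sum(x[contributions$branch == "risk"])
  overall <- (bs + rs) / 2
  list(benefit_sum = bs, risk_sum = rs, overall = overall,
       overall_rounded = round_half_up(overall))
}
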