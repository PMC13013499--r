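#' Monte Carlo propagation of pooled-estimate uncertainty
#'
#' Each pooled effect is resampled from its 95% CI — Normal on the MD
#' scale, Normal on the log-RR scale with the standard error recovered as
#' CI width / (2 * 1.96) — and pushed through the value model. Repeating
#' this gives a distribution of benefit-risk values, from which percentile
#' credible intervals, between-group superiority probabilities, and
#' difference summaries are read off. Draws are independent across criteria
#' and across groups.
#'
#' @name uncertainty
NULL

#' Monte Carlo settings
#'
#' @param iterations number of iterations (default 3000).
#' @param seed integer RNG seed (default 20250311).
#' @param clamp clamp partial-value scores into \[0, 100\] per iteration?
#' @param mode overall combination mode, see [overall_bra()].
#' @return an `mc_config` list.
#' @export
mc_config <- function(iterations = 3000, seed = 20250311, clamp = FALSE,
                      mode = c("weight_proportional", "mean_of_branches")) {
  mode <- match.arg(mode)
  if (iterations < 1) bra_abort("iterations must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed), clamp = clamp, mode = mode),
            class = "mc_config")
}

#' Sample effects from a pooled estimate
#'
#' MD: draws ~ Normal(effect, se) with se = (ci_high - ci_low) / (2 * 1.96).
#' RR: log draws ~ Normal(log effect, se_log) with
#' se_log = (log ci_high - log ci_low) / (2 * 1.96), exponentiated, so all
#' draws stay positive. A zero-width CI yields a constant sample.
#'
#' @param estimate a `pooled_estimate`.
#' @param n number of draws.
#' @return numeric vector of `n` effects on the natural scale. Does not
#'   seed the RNG; wrap in [withr::with_seed()]-style seeding or use
#'   [simulate_bra()] for reproducible runs.
#' @export
sample_pooled <- function(estimate, n) {
  stopifnot(inherits(estimate, "pooled_estimate"))
  if (!is.finite(estimate$ci_low) || !is.finite(estimate$ci_high)) {
    bra_abort("estimate must have a finite confidence interval")
  }
  z2 <- 2 * stats::qnorm(0.975)
  if (estimate$scale == "RR") {
    se <- (log(estimate$ci_high) - log(estimate$ci_low)) / z2
    if (se == 0) return(rep(estimate$effect, n))
    exp(stats::rnorm(n, log(estimate$effect), se))
  } else {
    se <- (estimate$ci_high - estimate$ci_low) / z2
    if (se == 0) return(rep(estimate$effect, n))
    stats::rnorm(n, estimate$effect, se)
  }
}

# internal: matrix of overall BRA draws for one group (no seeding here)
draw_bra_samples <- function(tree, estimates, config) {
  n <- config$iterations
  ids <- names(tree$criteria)
  score_mat <- matrix(0, nrow = n, ncol = length(ids),
                      dimnames = list(NULL, ids))
  present <- logical(length(ids)); names(present) <- ids
  for (id in ids) {
    e <- estimates[[id]]
    cr <- tree$criteria[[id]]
    if (is.null(e)) next  # absent: deterministic zero contribution
    present[id] <- TRUE
    x <- sample_pooled(e, n)
    s <- 100 * (x - cr$anchor_worst) / (cr$anchor_best - cr$anchor_worst)
    if (config$clamp) s <- pmin(100, pmax(0, s))
    score_mat[, id] <- s
  }
  w_b <- tree_weights(tree, "benefit")
  w_r <- tree_weights(tree, "risk")
  b <- score_mat[, names(w_b), drop = FALSE] %*% w_b / sum(w_b)
  r <- score_mat[, names(w_r), drop = FALSE] %*% w_r / sum(w_r)
  switch(config$mode,
    weight_proportional =
      (tree$branch_weight_benefit * b + tree$branch_weight_risk * r) / 100,
    mean_of_branches =
      (tree$branch_weight_benefit * b / 100 +
       tree$branch_weight_risk * r / 100) / 2)[, 1L]
}

# internal: stable per-group seed so each group's draws depend only on the
# group's own estimates and the base seed (common random numbers per group
# identity; makes compare_groups exactly antisymmetric)
group_seed <- function(base_seed, estimates) {
  key <- paste(vapply(names(estimates), function(id) {
    e <- estimates[[id]]
    if (is.null(e)) paste0(id, ":absent")
    else sprintf("%s:%s:%.10g:%.10g:%.10g", id, e$scale, e$effect,
                 e$ci_low, e$ci_high)
  }, character(1)), collapse = "|")
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  as.integer((as.numeric(base_seed) + h) %% 2147483647)
}

#' Monte Carlo distribution of the overall benefit-risk value
#'
#' Each iteration draws every present criterion's effect independently from
#' its pooled estimate, scores it, aggregates branches, and records the
#' overall value. Absent criteria (no estimate) contribute a deterministic
#' zero with their weight retained.
#'
#' @param tree a [criteria_tree()].
#' @param estimates named list of `pooled_estimate` objects (`NULL` =
#'   absent), as from [read_pooled_table()].
#' @param config an [mc_config()].
#' @param keep_samples retain the full sample vector in the result?
#' @return an `mc_summary` list: `mean`, `ci_low`, `ci_high` (2.5/97.5
#'   percentiles), `iterations`, `seed`, and optionally `samples`.
#' @export
simulate_bra <- function(tree, estimates, config = mc_config(),
                         keep_samples = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(group_seed(config$seed, estimates))
  x <- draw_bra_samples(tree, estimates, config)
  q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  out <- structure(list(mean = mean(x), ci_low = q[1], ci_high = q[2],
                        iterations = config$iterations, seed = config$seed),
                   class = "mc_summary")
  if (keep_samples) out$samples <- x
  out
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("BRA %.2f [95%% CI (%.2f, %.2f)] over %d iterations (seed %d)\n",
              x$mean, x$ci_low, x$ci_high, x$iterations, x$seed))
  invisible(x)
}

#' Probabilistic comparison of two alternatives
#'
#' Simulates both groups' benefit-risk values with independent draws per
#' group and summarises the paired per-iteration differences. Each group's
#' random stream is keyed to its own estimates (plus the base seed), so
#' swapping the two arguments maps `p_a_greater` to exactly
#' `1 - p_a_greater - p_tie`.
#'
#' @param tree a [criteria_tree()].
#' @param estimates_a,estimates_b named lists of pooled estimates for the
#'   two alternatives.
#' @param config an [mc_config()].
#' @return a `comparison_result` list: `p_a_greater`, `p_tie`, `diff_mean`,
#'   `diff_ci_low`, `diff_ci_high`, `mean_a`, `mean_b`, `iterations`, `seed`.
#' @export
compare_groups <- function(tree, estimates_a, estimates_b,
                           config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(group_seed(config$seed, estimates_a))
  a <- draw_bra_samples(tree, estimates_a, config)
  set.seed(group_seed(config$seed, estimates_b))
  b <- draw_bra_samples(tree, estimates_b, config)
  d <- a - b
  q <- unname(stats::quantile(d, c(0.025, 0.975), type = 7))
  structure(list(p_a_greater = mean(a > b), p_tie = mean(a == b),
                 diff_mean = mean(d), diff_ci_low = q[1], diff_ci_high = q[2],
                 mean_a = mean(a), mean_b = mean(b),
                 iterations = config$iterations, seed = config$seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "P(A > B) = %.2f%%; difference %.2f [95%% CI (%.2f, %.2f)]; %d iterations\n",
    100 * x$p_a_greater, x$diff_mean, x$diff_ci_low, x$diff_ci_high,
    x$iterations))
  invisible(x)
}

#' Weight-sweep sensitivity analysis
#'
#' Sweeps the benefit-branch weight over \[0, 100\] (risk weight = 100 -
#' benefit weight; within-branch weights rescale proportionally, which
#' leaves branch values unchanged), recording both alternatives'
#' deterministic overall values at every step. The ranking of two
#' alternatives is declared stable when no weight within `threshold`
#' percentage points of the tree's benefit weight reverses it.
#'
#' @param tree a [criteria_tree()].
#' @param estimates_a,estimates_b pooled estimates for the two alternatives.
#' @param step sweep resolution in percentage points (default 1).
#' @param threshold stability rule: the smallest flip distance that still
#'   counts as stable must exceed this many percentage points (default 20).
#' @return a `sensitivity_result` list: `sweep` (data frame
#'   `benefit_weight`, `bra_a`, `bra_b`), `crossing` (benefit weight where
#'   the two linear curves intersect, or `NA`), `flip_threshold` (absolute
#'   distance from the tree's benefit weight to the nearest reversal, or
#'   `NA` when no reversal occurs), `stable`.
#' @export
weight_sensitivity <- function(tree, estimates_a, estimates_b, step = 1,
                               threshold = 20) {
  sc_a <- score_estimates(tree, estimates_a)
  sc_b <- score_estimates(tree, estimates_b)
  b_a <- branch_value(sc_a, tree, "benefit"); r_a <- branch_value(sc_a, tree, "risk")
  b_b <- branch_value(sc_b, tree, "benefit"); r_b <- branch_value(sc_b, tree, "risk")
  w <- seq(0, 100, by = step)
  bra_a <- (w * b_a + (100 - w) * r_a) / 100
  bra_b <- (w * b_b + (100 - w) * r_b) / 100
  # the two curves are linear in w; analytic crossing point
  slope <- (b_a - r_a) - (b_b - r_b)
  crossing <- if (slope == 0) NA_real_ else 100 * (r_b - r_a) / slope
  if (!is.na(crossing) && (crossing < 0 || crossing > 100)) crossing <- NA_real_
  w0 <- tree$branch_weight_benefit
  sign0 <- sign(bra_a[which.min(abs(w - w0))] - bra_b[which.min(abs(w - w0))])
  flipped <- sign(bra_a - bra_b) != sign0 & sign(bra_a - bra_b) != 0
  flip_threshold <- if (any(flipped)) min(abs(w[flipped] - w0)) else NA_real_
  structure(list(
    sweep = data.frame(benefit_weight = w, bra_a = bra_a, bra_b = bra_b),
    crossing = crossing, flip_threshold = flip_threshold,
    stable = is.na(flip_threshold) || flip_threshold > threshold,
    branch_values = c(benefit_a = b_a, risk_a = r_a,
                      benefit_b = b_b, risk_b = r_b)),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Weight sensitivity: crossing at benefit weight %s; %s\n",
              if (is.na(x$crossing)) "none" else sprintf("%.2f", x$crossing),
              if (x$stable) "ranking stable" else "ranking flips within threshold"))
  invisible(x)
}
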