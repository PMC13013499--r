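#' Synthetic data generators
#'
#' Seed-deterministic generators that emulate the statistical structure the
#' pipeline assumes: two-arm randomised trials reported as per-arm summary
#' statistics (continuous outcomes) or 2x2 counts (adverse events), with a
#' specified true effect and log-scale/normal-scale between-trial
#' heterogeneity; and expert Likert panels with tunable consensus. They let
#' every stage — pooling, scoring, Monte Carlo — be exercised end to end
#' without any external data.
#'
#' @name synthetic_data
NULL

# draw k integers uniformly from [lo, hi]; safe when lo == hi
# (sample(x, ...) would treat a scalar x as 1:x)
resample_range <- function(range, k) {
  vals <- seq(range[1], range[2])
  vals[sample.int(length(vals), k, replace = TRUE)]
}

#' Generate continuous two-arm trials
#'
#' Trial i has a true mean difference theta_i ~ Normal(true_md, tau^2).
#' Control arms are centred at 0; arm means and SDs are the sample
#' statistics of Normal outcomes with the per-trial outcome SD drawn
#' uniformly from `sd_range` and per-arm sizes uniformly from `n_range`.
#'
#' @param k number of trials (>= 1).
#' @param true_md true mean difference (negative = improvement under the
#'   pipeline's direction convention).
#' @param tau between-trial SD of true effects (>= 0).
#' @param n_range integer range of per-arm sizes, e.g. `c(30, 80)`.
#' @param sd_range range of the outcome SD.
#' @param seed RNG seed.
#' @return data frame of [pool_md()] input rows.
#' @export
gen_continuous_trials <- function(k, true_md, tau = 0, n_range = c(30, 80),
                                  sd_range = c(1, 3), seed = 1) {
  if (k < 1) bra_abort("k must be >= 1")
  if (tau < 0) bra_abort("tau must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  theta <- stats::rnorm(k, true_md, tau)
  n_t <- resample_range(n_range, k)
  n_c <- resample_range(n_range, k)
  sd_true <- stats::runif(k, sd_range[1], sd_range[2])
  sample_arm <- function(n, mu, s) {
    x <- stats::rnorm(n, mu, s)
    c(mean = mean(x), sd = stats::sd(x))
  }
  rows <- lapply(seq_len(k), function(i) {
    tr <- sample_arm(n_t[i], theta[i], sd_true[i])
    ct <- sample_arm(n_c[i], 0, sd_true[i])
    data.frame(trial_id = sprintf("trial_%02d", i),
               n_t = n_t[i], mean_t = tr["mean"], sd_t = tr["sd"],
               n_c = n_c[i], mean_c = ct["mean"], sd_c = ct["sd"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate binary two-arm trials
#'
#' Control events ~ Binomial(n_c, control_risk); treatment events ~
#' Binomial(n_t, min(1, control_risk * RR_i)) with the per-trial risk ratio
#' RR_i log-normally dispersed around `true_rr` with log-scale SD `tau`.
#'
#' @param k number of trials (>= 1).
#' @param true_rr true risk ratio (> 0).
#' @param tau log-scale SD of per-trial true risk ratios (>= 0).
#' @param control_risk baseline event probability in (0, 1).
#' @param n_range integer range of per-arm sizes.
#' @param seed RNG seed.
#' @return data frame of [pool_rr()] input rows.
#' @export
gen_binary_trials <- function(k, true_rr, tau = 0, control_risk = 0.1,
                              n_range = c(50, 150), seed = 1) {
  if (k < 1) bra_abort("k must be >= 1")
  if (true_rr <= 0) bra_abort("true_rr must be positive")
  if (control_risk <= 0 || control_risk >= 1) {
    bra_abort("control_risk must be in (0, 1)")
  }
  if (any(n_range < 1)) bra_abort("arm sizes must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rr_i <- exp(stats::rnorm(k, log(true_rr), tau))
  n_t <- resample_range(n_range, k)
  n_c <- resample_range(n_range, k)
  data.frame(trial_id = sprintf("trial_%02d", seq_len(k)),
             events_t = stats::rbinom(k, n_t, pmin(1, control_risk * rr_i)),
             n_t = n_t,
             events_c = stats::rbinom(k, n_c, control_risk),
             n_c = n_c, stringsAsFactors = FALSE)
}

#' Generate an expert Likert panel
#'
#' Scores are a discretised latent Normal: each criterion/dimension has a
#' target mean, experts deviate from it with SD (1 - consensus) * 2, and
#' the draw is rounded and clipped into 1..5. Consensus 1 makes every
#' expert give the (rounded) target score; lower consensus inflates the
#' dispersion, raising the coefficient of variation and lowering rank
#' concordance. Self-assessments are drawn from {3, 4, 5}.
#'
#' @param n_experts number of experts (>= 2).
#' @param target_means named numeric vector or one-row-per-criterion data
#'   frame: target mean score per criterion (used for both dimensions
#'   unless `feasibility_means` is given).
#' @param consensus dispersion control in \[0, 1\].
#' @param feasibility_means optional separate targets for the feasibility
#'   dimension.
#' @param seed RNG seed.
#' @return list with `responses` (panel data frame as consumed by
#'   [panel_stats()]), `self_assessments`, `n_distributed`, `n_valid`.
#' @export
gen_expert_panel <- function(n_experts, target_means, consensus = 0.8,
                             feasibility_means = NULL, seed = 1) {
  if (n_experts < 2) bra_abort("n_experts must be >= 2")
  if (consensus < 0 || consensus > 1) bra_abort("consensus must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(names(target_means))) {
    bra_abort("target_means must be a named vector (names = criterion ids)")
  }
  feas <- feasibility_means %||% target_means
  sdev <- (1 - consensus) * 2
  grids <- expand.grid(expert_id = sprintf("expert_%02d", seq_len(n_experts)),
                       criterion_id = names(target_means),
                       dimension = c("importance", "feasibility"),
                       stringsAsFactors = FALSE)
  mu <- ifelse(grids$dimension == "importance",
               target_means[grids$criterion_id], feas[grids$criterion_id])
  x <- if (sdev == 0) mu else stats::rnorm(nrow(grids), mu, sdev)
  grids$score <- pmin(5L, pmax(1L, as.integer(round(x))))
  sa <- data.frame(expert_id = sprintf("expert_%02d", seq_len(n_experts)),
                   judgment_basis = sample(3:5, n_experts, replace = TRUE),
                   familiarity = sample(3:5, n_experts, replace = TRUE),
                   stringsAsFactors = FALSE)
  list(responses = validate_panel(grids), self_assessments = sa,
       n_distributed = n_experts, n_valid = n_experts)
}
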