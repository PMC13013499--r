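#' Random-effects pooling of two-arm trial summaries
#'
#' Each benefit criterion is pooled as a mean difference (MD) from per-arm
#' (n, mean, SD) summaries; each risk criterion as a risk ratio (RR) from
#' 2x2 counts, pooled on the log scale. Between-study heterogeneity is
#' handled by the DerSimonian-Laird moment estimator, the random-effects
#' default of the standard meta-analysis tools this pipeline mirrors.
#'
#' @name evidence
NULL

new_pooled_estimate <- function(scale, effect, se, ci_low, ci_high,
                                tau2, q_stat, k) {
  structure(list(scale = scale, effect = effect, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 tau2 = tau2, q_stat = q_stat, k = k),
            class = "pooled_estimate")
}

#' Construct a pooled estimate from reported summary values
#'
#' Builds a `pooled_estimate` directly from a published effect and 95% CI
#' (e.g. a printed meta-analysis table), back-computing the standard error
#' from the CI width: SE = width / (2 * 1.96), on the log scale for RR.
#'
#' @param scale `"MD"` or `"RR"`.
#' @param effect pooled effect on the natural scale.
#' @param ci_low,ci_high 95% confidence bounds on the natural scale.
#' @param k number of studies, if known.
#' @return a `pooled_estimate`.
#' @export
pooled_estimate <- function(scale = c("MD", "RR"), effect, ci_low, ci_high,
                            k = NA_integer_) {
  scale <- match.arg(scale)
  if (scale == "RR") {
    if (effect <= 0 || ci_low <= 0 || ci_high <= 0) {
      bra_abort("RR effect and CI must be positive")
    }
    se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  } else {
    se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  }
  if (ci_low > effect || effect > ci_high) {
    bra_abort("effect must lie inside its confidence interval")
  }
  new_pooled_estimate(scale, effect, se, ci_low, ci_high,
                      tau2 = NA_real_, q_stat = NA_real_, k = k)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g, 95%% CI (%.4g, %.4g)",
              x$scale, x$effect, x$ci_low, x$ci_high))
  if (is.finite(x$tau2)) cat(sprintf(", tau^2 = %.4g", x$tau2))
  if (!is.na(x$k)) cat(sprintf(", k = %d", as.integer(x$k)))
  cat("\n")
  invisible(x)
}

# internal: DerSimonian-Laird pooling of per-study effects yi with
# within-study variances vi; returns list(mu, se, tau2, q)
dl_pool <- function(yi, vi) {
  k <- length(yi)
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fe)^2)
  tau2 <- if (k > 1L) {
    c_const <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - (k - 1)) / c_const)
  } else 0
  w_re <- 1 / (vi + tau2)
  mu <- sum(w_re * yi) / sum(w_re)
  list(mu = mu, se = sqrt(1 / sum(w_re)), tau2 = tau2, q = q)
}

#' Pool continuous two-arm trials (mean difference)
#'
#' Per-trial MD = mean_t - mean_c with variance sd_t^2/n_t + sd_c^2/n_c,
#' combined by DerSimonian-Laird random effects. The 95% CI uses the normal
#' multiplier 1.96. With a single trial the pooled result is that trial.
#'
#' @param trials data frame with columns `trial_id`, `n_t`, `mean_t`,
#'   `sd_t`, `n_c`, `mean_c`, `sd_c`.
#' @return a `pooled_estimate` with scale `"MD"`.
#' @export
pool_md <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    bra_abort("no trials to pool")
  }
  need <- c("n_t", "mean_t", "sd_t", "n_c", "mean_c", "sd_c")
  stopifnot(all(need %in% names(trials)))
  if (any(trials$n_t < 1 | trials$n_c < 1)) bra_abort("arm sizes must be >= 1")
  if (any(trials$sd_t < 0 | trials$sd_c < 0)) bra_abort("SDs must be >= 0")
  yi <- trials$mean_t - trials$mean_c
  vi <- trials$sd_t^2 / trials$n_t + trials$sd_c^2 / trials$n_c
  if (any(vi <= 0)) {
    bra_abort("trial with zero variance in both arms cannot be weighted")
  }
  fit <- dl_pool(yi, vi)
  z <- stats::qnorm(0.975)
  new_pooled_estimate("MD", fit$mu, fit$se,
                      fit$mu - z * fit$se, fit$mu + z * fit$se,
                      fit$tau2, fit$q, length(yi))
}

#' Pool binary two-arm trials (risk ratio)
#'
#' Per-trial log RR with variance 1/a - 1/n_t + 1/c - 1/n_c, combined by
#' inverse-variance DerSimonian-Laird on the log scale and reported on the
#' natural scale. Trials with a zero cell in exactly one arm get a 0.5
#' continuity correction added to all four cells; trials with zero events
#' in both arms are excluded from pooling.
#'
#' @param trials data frame with columns `trial_id`, `events_t`, `n_t`,
#'   `events_c`, `n_c`.
#' @return a `pooled_estimate` with scale `"RR"`; the number of excluded
#'   double-zero trials is attached as attribute `"n_excluded"`.
#' @export
pool_rr <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    bra_abort("no trials to pool")
  }
  need <- c("events_t", "n_t", "events_c", "n_c")
  stopifnot(all(need %in% names(trials)))
  if (any(trials$events_t < 0 | trials$events_c < 0) ||
      any(trials$events_t > trials$n_t) || any(trials$events_c > trials$n_c)) {
    bra_abort("event counts must satisfy 0 <= events <= n")
  }
  double_zero <- trials$events_t == 0 & trials$events_c == 0
  est <- trials[!double_zero, , drop = FALSE]
  if (nrow(est) == 0L) bra_abort("no estimable trials (all double-zero)")
  a <- est$events_t; n1 <- est$n_t; c_ <- est$events_c; n2 <- est$n_c
  single_zero <- (a == 0) != (c_ == 0)
  a[single_zero] <- a[single_zero] + 0.5
  c_[single_zero] <- c_[single_zero] + 0.5
  n1[single_zero] <- n1[single_zero] + 1
  n2[single_zero] <- n2[single_zero] + 1
  yi <- log((a / n1) / (c_ / n2))
  vi <- 1 / a - 1 / n1 + 1 / c_ - 1 / n2
  fit <- dl_pool(yi, vi)
  z <- stats::qnorm(0.975)
  out <- new_pooled_estimate("RR", exp(fit$mu), fit$se,
                             exp(fit$mu - z * fit$se),
                             exp(fit$mu + z * fit$se),
                             fit$tau2, fit$q, length(yi))
  attr(out, "n_excluded") <- sum(double_zero)
  out
}

#' Pool a mixed trial table criterion by criterion
#'
#' Splits a long trial table on `criterion_id` and pools each criterion
#' with [pool_md()] (rows carrying arm means) or [pool_rr()] (rows carrying
#' event counts).
#'
#' @param trials data frame with a `criterion_id` column plus either the
#'   continuous or the binary arm columns per criterion.
#' @return a named list of `pooled_estimate` objects.
#' @export
pool_by_criterion <- function(trials) {
  stopifnot("criterion_id" %in% names(trials))
  split_tr <- split(trials, trials$criterion_id)
  lapply(split_tr, function(d) {
    if (all(is.finite(d$mean_t %||% NA))) pool_md(d) else pool_rr(d)
  })
}

#' Tabulate pooled estimates
#'
#' @param estimates named list of `pooled_estimate` objects.
#' @return data frame with one row per criterion: `criterion_id`, `scale`,
#'   `effect`, `ci_low`, `ci_high`, `tau2`, `q_stat`, `k`.
#' @export
pooled_table <- function(estimates) {
  do.call(rbind, lapply(names(estimates), function(id) {
    e <- estimates[[id]]
    data.frame(criterion_id = id, scale = e$scale, effect = e$effect,
               ci_low = e$ci_low, ci_high = e$ci_high, tau2 = e$tau2,
               q_stat = e$q_stat, k = e$k, stringsAsFactors = FALSE)
  }))
}

#' Read a table of pooled estimates from CSV
#'
#' Expects columns `criterion_id`, `scale`, `effect`, `ci_low`, `ci_high`;
#' an optional `group` column selects one subset. Rows with a missing
#' effect represent criteria with no estimable evidence (e.g. no events in
#' any trial) and are returned as `NULL` entries, which downstream scoring
#' treats as absent.
#'
#' @param path CSV path.
#' @param group if the file has a `group` column, which group to read.
#' @return named list of `pooled_estimate` (or `NULL` for absent criteria).
#' @export
read_pooled_table <- function(path, group = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(group)) {
    stopifnot("group" %in% names(d))
    d <- d[d$group == group, , drop = FALSE]
    if (nrow(d) == 0L) bra_abort(sprintf("no rows for group '%s'", group))
  }
  out <- lapply(seq_len(nrow(d)), function(i) {
    if (is.na(d$effect[i])) return(NULL)
    pooled_estimate(d$scale[i], d$effect[i], d$ci_low[i], d$ci_high[i],
                    k = if ("k" %in% names(d)) d$k[i] else NA_integer_)
  })
  names(out) <- d$criterion_id
  out
}
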