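test_that("criterion statistics match hand arithmetic", {
  cases <- list(
    # scores, mean, max_score_freq, cv (population SD / mean)
    list(c(5, 5, 5, 5), 5.0, 1.0, 0.0),
    list(c(5, 5, 4, 3), 4.25, 0.5, sqrt(0.6875) / 4.25),
    list(c(rep(5, 19), rep(4, 3)), 107 / 22, 19 / 22,
         sqrt((19 * (5 - 107/22)^2 + 3 * (4 - 107/22)^2) / 22) / (107/22))
  )
  for (cs in cases) {
    st <- compute_criterion_stats(make_panel(cs[[1]]), "crit", "importance")
    expect_equal(st$mean, cs[[2]])
    expect_equal(st$max_score_freq, cs[[3]])
    expect_equal(st$cv, cs[[4]], tolerance = 1e-12)
    expect_equal(st$n_raters, length(cs[[1]]))
  }
  # the 19x5 + 3x4 roster reconstructs the published panel row up to rounding
  st <- compute_criterion_stats(make_panel(c(rep(5, 19), rep(4, 3))),
                                "crit", "importance")
  expect_equal(round(st$mean, 2), 4.86)
  expect_equal(round(st$max_score_freq, 2), 0.86)
  expect_equal(round(st$cv, 2), 0.07)
})

test_that("criterion statistics are permutation-invariant and error on empty", {
  scores <- c(3, 5, 4, 5, 2)
  a <- compute_criterion_stats(make_panel(scores), "crit", "importance")
  b <- compute_criterion_stats(make_panel(rev(scores)), "crit", "importance")
  expect_equal(a$mean, b$mean)
  expect_equal(a$cv, b$cv)
  expect_error(
    compute_criterion_stats(make_panel(5), "crit", "feasibility"),
    class = "bramcda_empty_criterion")
  # unanimous panel keeps CV at zero when an expert's copy is appended
  pan <- make_panel(rep(4, 6))
  pan2 <- rbind(pan, data.frame(expert_id = 7, criterion_id = "crit",
                                dimension = "importance", score = 4))
  expect_equal(compute_criterion_stats(pan2, "crit", "importance")$cv, 0)
})

test_that("panel validation rejects malformed input", {
  expect_error(
    compute_criterion_stats(make_panel(c(0, 5)), "crit", "importance"),
    "1..5")
  bad <- rbind(make_panel(5), make_panel(4))  # same expert scores twice
  expect_error(compute_criterion_stats(bad, "crit", "importance"),
               "at most one score")
})

test_that("screening the published panel table yields the ten model criteria", {
  stats <- fuzi_panel_stats()
  kept <- screen_criteria(stats, fuzi_screening_rule())
  expect_length(kept, 10)
  risk_ids <- c("adr_incidence", "cardiovascular_adr", "hematologic_adr",
                "liver_kidney_adr", "allergy_adr")
  benefit_ids <- c("swollen_joints", "pressure_pain_joints",
                   "morning_stiffness", "esr", "rheumatoid_factor")
  expect_setequal(kept, c(risk_ids, benefit_ids))
  # ordered by descending importance mean, alphabetical on ties
  expect_equal(kept[1:2], c("rheumatoid_factor", "swollen_joints"))
})

test_that("screening applies thresholds conjunctively and flags missing dimensions", {
  mk <- function(id, imp_mean, fea_mean = 4.5, freq = 0.5, cv = 0.1) {
    data.frame(criterion_id = id,
               dimension = c("importance", "feasibility"),
               mean = c(imp_mean, fea_mean),
               max_score_freq = freq, cv = cv, stringsAsFactors = FALSE)
  }
  # boundary: importance mean 3.49 excluded however good the rest is
  st <- rbind(mk("good", 5.0, 5.0, 1.0, 0.0), mk("boundary", 3.49))
  kept <- screen_criteria(st, screening_rule())
  expect_equal(as.character(kept), "good")
  # a criterion scored in one dimension only is an error naming it
  st_half <- mk("lonely", 5)[1L, ]
  expect_error(screen_criteria(st_half, screening_rule()), "lonely")
})

test_that("percentage weights follow the rank-tally formula", {
  # one expert ranking 10 criteria 1st..10th with values 10..1
  t1 <- data.frame(criterion_id = paste0("c", 1:10),
                   rank_position = 1:10, count = 1)
  w <- percentage_weights(t1, n_valid = 1, rank_values = 10:1)
  expect_equal(unname(w["c1"]), 10 / 55)
  expect_equal(unname(w["c10"]), 1 / 55)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # two experts both ranking criterion A first
  t2 <- data.frame(criterion_id = "A", rank_position = 1, count = 2)
  wa <- percentage_weights(t2, n_valid = 2, rank_values = 10:1)
  expect_equal(unname(wa), 20 / 110)
  # a criterion never ranked weighs zero
  t3 <- data.frame(criterion_id = "Z", rank_position = 1, count = 0)
  expect_equal(unname(percentage_weights(t3, 2, 10:1)), 0)
  expect_error(percentage_weights(t2, n_valid = 1, rank_values = 10:1),
               "exceed")
})

test_that("complete random rankings always give weights summing to one", {
  set.seed(42)
  for (rep in 1:20) {
    n_crit <- sample(3:10, 1)
    n_exp <- sample(2:8, 1)
    counts <- matrix(0L, n_crit, n_crit)  # criterion x rank position
    for (e in seq_len(n_exp)) {
      perm <- sample(n_crit)
      counts[cbind(seq_len(n_crit), perm)] <-
        counts[cbind(seq_len(n_crit), perm)] + 1L
    }
    tal <- data.frame(criterion_id = rep(paste0("c", seq_len(n_crit)), n_crit),
                      rank_position = rep(seq_len(n_crit), each = n_crit),
                      count = as.vector(counts))
    w <- percentage_weights(tal, n_valid = n_exp,
                            rank_values = rev(seq_len(n_crit)))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("Kendall's W matches the brute-force rank-sum formula", {
  ident <- matrix(rep(1:4, each = 3), nrow = 3, byrow = FALSE)
  ident <- rbind(1:4, 1:4, 1:4)
  expect_equal(kendall_w(ident)$w, 1)
  expect_equal(kendall_w(rbind(1:2, 2:1))$w, 0)
  r33 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  kw <- kendall_w(r33)
  expect_equal(kw$w, kendall_w_bruteforce(r33), tolerance = 1e-12)
  expect_equal(kw$w, 4 / 9, tolerance = 1e-12)
  expect_equal(kw$chisq, 3 * 2 * 4 / 9, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  # exhaustive check over all 3-expert rankings of 3 items (no ties)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    r <- rbind(perms[i, ], perms[j, ], perms[k, ])
    expect_equal(kendall_w(r)$w, kendall_w_bruteforce(r), tolerance = 1e-12)
  }
  expect_error(kendall_w(matrix(1:3, nrow = 1)), "two experts")
})

test_that("tied ranks reduce the concordance denominator correctly", {
  # with mid-rank ties, W of identical tied rankings is still 1
  tied <- rbind(c(1.5, 1.5, 3), c(1.5, 1.5, 3))
  expect_equal(kendall_w(tied)$w, 1, tolerance = 1e-12)
})

test_that("authority coefficient averages the two rescaled self-ratings", {
  sa <- function(j, f, n = 3) {
    data.frame(expert_id = seq_len(n), judgment_basis = j, familiarity = f)
  }
  expect_equal(authority_coefficient(sa(5, 5)), 1.0)
  expect_equal(authority_coefficient(sa(4, 3)), 0.7)
  expect_equal(authority_coefficient(sa(5, 1, n = 1)), 0.6)
  empty <- data.frame(expert_id = integer(0), judgment_basis = integer(0),
                      familiarity = integer(0))
  expect_error(authority_coefficient(empty), "empty")
})
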