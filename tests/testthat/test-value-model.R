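# printed per-criterion scores of the two dose groups, in tree order
published_scores <- list(
  low_dose = c(pressure_pain_joints = 51, swollen_joints = 26,
               morning_stiffness = 48, esr = 25, rheumatoid_factor = 60,
               adr_incidence = 58, cardiovascular_adr = NA,
               hematologic_adr = 74, liver_kidney_adr = 74,
               allergy_adr = 34),
  high_dose = c(pressure_pain_joints = 44, swollen_joints = 25,
                morning_stiffness = 58, esr = 22, rheumatoid_factor = 57,
                adr_incidence = 64, cardiovascular_adr = NA,
                hematologic_adr = 54, liver_kidney_adr = 55,
                allergy_adr = NA))

test_that("linear partial-value scores interpolate between the anchors", {
  tender <- criterion("tender", "benefit", 11.8, "MD", -5, 0)
  expect_equal(linear_score(-2.53, tender)$score, 50.6, tolerance = 1e-12)
  expect_equal(linear_score(-5, tender)$score, 100)
  expect_equal(linear_score(0, tender)$score, 0)
  rr <- criterion("adr", "risk", 15.3, "RR", 0, 1)
  expect_equal(linear_score(0.42, rr)$score, 58, tolerance = 1e-12)
  # beyond-anchor effects exceed the bounds unless clamped
  expect_gt(linear_score(-6, tender)$score, 100)
  expect_equal(linear_score(-6, tender, clamp = TRUE)$score, 100)
  expect_equal(linear_score(1.4, rr, clamp = TRUE)$score, 0)
  # missing effect marks the criterion absent
  sc <- linear_score(NA, tender)
  expect_false(sc$present)
})

test_that("scores are invariant under common rescaling of effect and anchors", {
  set.seed(9)
  for (i in 1:20) {
    best <- runif(1, -50, -1); worst <- runif(1, 0, 10)
    x <- runif(1, best, worst)
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    cr1 <- criterion("c", "benefit", 10, "MD", best, worst)
    cr2 <- criterion("c", "benefit", 10, "MD", a * best + b, a * worst + b)
    expect_equal(linear_score(x, cr1)$score,
                 linear_score(a * x + b, cr2)$score, tolerance = 1e-8)
  }
})

test_that("every published dose-group score is reproduced from its pooled effect", {
  tree <- fuzi_tree()
  for (grp in names(published_scores)) {
    sc <- score_estimates(tree, fuzi_pooled(grp))
    got <- round_half_up(sc$score)
    names(got) <- sc$criterion_id
    exp_sc <- published_scores[[grp]]
    expect_equal(got[!is.na(exp_sc)], exp_sc[!is.na(exp_sc)])
    expect_true(all(!sc$present[is.na(exp_sc)]))
  }
})

test_that("branch values treat event-free criteria as zero with weight retained", {
  tree <- fuzi_tree()
  sc_low <- score_estimates(tree, fuzi_pooled("low_dose"))
  sc_high <- score_estimates(tree, fuzi_pooled("high_dose"))
  expect_equal(branch_value(sc_low, tree, "risk"), 48.22, tolerance = 1e-3)
  expect_equal(round_half_up(branch_value(sc_low, tree, "risk")), 48)
  expect_equal(round_half_up(branch_value(sc_high, tree, "risk")), 39)
  expect_equal(round_half_up(branch_value(sc_low, tree, "benefit")), 43)
  expect_equal(round_half_up(branch_value(sc_high, tree, "benefit")), 43)
})

test_that("branch value is a weighted mean: all-100 scores give 100", {
  tree <- fuzi_tree()
  full <- data.frame(criterion_id = names(tree$criteria), score = 100,
                     present = TRUE)
  expect_equal(branch_value(full, tree, "risk"), 100)
  expect_equal(branch_value(full, tree, "benefit"), 100)
})

test_that("branch value is monotone in every individual score", {
  tree <- fuzi_tree()
  base <- data.frame(criterion_id = names(tree$criteria),
                     score = 50, present = TRUE)
  b0 <- branch_value(base, tree, "risk")
  for (id in c("adr_incidence", "allergy_adr")) {
    up <- base
    up$score[up$criterion_id == id] <- 60
    expect_gt(branch_value(up, tree, "risk"), b0)
  }
})

test_that("overall benefit-risk values reproduce the published 46 and 41", {
  tree <- fuzi_tree()
  low <- bra_value(tree, fuzi_pooled("low_dose"))
  high <- bra_value(tree, fuzi_pooled("high_dose"))
  expect_equal(low$overall_rounded, 46)
  expect_equal(high$overall_rounded, 41)
  # identity: when per-branch weights sum exactly to the branch weights,
  # the weight-proportional overall equals the total contribution sum
  st <- simple_tree()
  res <- bra_value(st, list(b1 = const_estimate(-63),
                            r1 = const_estimate(-38)))
  ct_s <- contribution_table(res, st)
  expect_equal(res$overall, sum(ct_s$contribution), tolerance = 1e-12)
  # on the published tree (benefit weights sum to 49.1 against a 49%
  # branch weight) the identity holds to the bookkeeping rounding
  ct <- contribution_table(low, tree)
  expect_equal(low$overall, sum(ct$contribution), tolerance = 0.005)
  # equal branch values pass through unchanged
  eq <- overall_bra(70, 70, tree, mode = "weight_proportional")
  expect_equal(eq$overall, 70)
})

test_that("contribution table multiplies weight by score over 100", {
  tree <- fuzi_tree()
  res <- bra_value(tree, fuzi_pooled("low_dose"))
  ct <- contribution_table(res, tree)
  i <- match("pressure_pain_joints", ct$criterion_id)
  expect_equal(ct$contribution[i], 11.8 * 50.6 / 100, tolerance = 1e-9)
  j <- match("cardiovascular_adr", ct$criterion_id)
  expect_equal(ct$contribution[j], 0)
  expect_false(ct$present[j])
  # branch subtotal = branch value x branch weight sum / 100
  sub <- attr(ct, "subtotals")
  expect_equal(unname(sub["risk"]),
               branch_value(res$scores, tree, "risk") * 51 / 100,
               tolerance = 1e-9)
})

test_that("published duration-group contributions combine to 41, 45 and 36", {
  c1 <- combine_contributions(fuzi_contributions("within_2_months"))
  expect_equal(c1$benefit_sum, 44.2, tolerance = 1e-9)
  expect_equal(c1$risk_sum, 37.4, tolerance = 1e-9)
  expect_equal(c1$overall_rounded, 41)
  c2 <- combine_contributions(fuzi_contributions("months_2_to_3"))
  expect_equal(c2$overall_rounded, 45)
  # the source table's third column is internally inconsistent: the printed
  # contributions recompute to 36, not the printed 37
  c3 <- combine_contributions(fuzi_contributions("over_3_months"))
  expect_equal(c3$overall, 36.3, tolerance = 1e-9)
  expect_equal(c3$overall_rounded, 36)
})

test_that("clamped pipelines keep every value inside 0..100", {
  tree <- fuzi_tree()
  wild <- list(pressure_pain_joints = const_estimate(-12),   # beyond best
               adr_incidence = const_estimate(1.8, "RR"))    # beyond worst
  res <- bra_value(tree, wild, clamp = TRUE)
  expect_true(all(res$scores$score[res$scores$present] >= 0 &
                  res$scores$score[res$scores$present] <= 100))
  expect_gte(res$overall, 0)
  expect_lte(res$overall, 100)
})

test_that("tree construction enforces the weight bookkeeping", {
  expect_error(criteria_tree(list(criterion("a", "benefit", 30, "MD", -1, 0),
                                  criterion("b", "risk", 51, "RR", 0, 1)),
                             branch_weight_benefit = 49,
                             branch_weight_risk = 51),
               "sum to 30")
  expect_error(criteria_tree(list(criterion("a", "benefit", 49, "MD", -1, 0),
                                  criterion("b", "risk", 51, "RR", 0, 1)),
                             branch_weight_benefit = 40,
                             branch_weight_risk = 51),
               "sum to 100")
  expect_error(criterion("a", "benefit", 10, "MD", 0, 0), "anchors")
})
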