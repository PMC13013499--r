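---
title: "Methods: quantitative benefit-risk assessment by MCDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative benefit-risk assessment by MCDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bramcda)
```

This vignette documents the statistical model behind `bramcda`, the
conventions and numerical choices it commits to, and what the synthetic
generators do and do not emulate. The running example is the package's
worked case: decoctions containing Fuzi (processed *Aconitum carmichaelii*
root, a cardiotoxic botanical) against standard treatment in rheumatoid
arthritis, whose published summary inputs ship as fixtures.

## 1. Delphi screening and weighting

Experts rate each candidate criterion on 1–5 Likert scales in two
dimensions, importance and feasibility. Three consensus statistics are
computed per criterion and dimension from the m collected scores C_i:

- mean M = Σ C_i / m;
- full-score frequency K = #(C_i = 5) / m;
- coefficient of variation V = σ/M.

**Population vs sample SD.** V uses the population SD (divisor m). This is
the convention that reproduces the shipped panel table: a 22-expert roster
of nineteen 5s and three 4s gives M = 4.86, K = 0.86, V = 0.07, matching
the published row for the leading risk criterion; the sample SD would give
V = 0.072 → 0.07 as well here, but diverges on small panels. The divisor is
configurable (`sd_type`).

**Conjunctive screening.** A criterion is retained iff M ≥ 3.5, K ≥ 0.2
and V < 0.25 hold in *both* dimensions. The conjunctive reading is the
only one under which the shipped 26-candidate panel table yields exactly
the ten-criterion model (five benefit, five risk) — a disjunctive or
single-dimension rule keeps more. Two retained organ-damage criteria
(liver, kidney) are merged after screening via the rule's `merge_map`,
because the final model treats "liver and kidney damage" as one criterion
while the panel scored them separately.

**Weights.** Percentage weighting from rank tallies:
weight_j = Σ_i w_i N_ij / (N Σ_i w_i), with rank values w = 10…1 for ten
criteria and N valid questionnaires. For complete rankings the weights sum
to 1 exactly, which the tests assert at 1e-12. Tied ranks in elicitation
should be entered as mid-rank tallies; Kendall's W is computed with the
standard tie correction and its χ² approximation m(n−1)W on n−1 degrees of
freedom. The authority coefficient uses the conventional
Cr = (Ca + Cs)/2 with both self-ratings rescaled by /5; published panels
rarely disclose the raw self-assessments, so this statistic is a quality
descriptor, not a reproduction target.

## 2. Random-effects pooling

Per-criterion evidence is pooled with the DerSimonian–Laird moment
estimator, implemented from its closed form: per-trial effects y_i with
within-trial variances v_i give Q = Σ w_i (y_i − ȳ_FE)², τ² = max(0,
(Q − (k−1))/C) with C = Σw − Σw²/Σw, and the pooled effect is the
inverse-variance mean with weights 1/(v_i + τ²). The tests cross-check
this against `metafor::rma(method = "DL")` on generated trials and against
a hand-computed two-study oracle to 1e-10.

Conventions, chosen to match the mainstream meta-analysis tools whose
output the value model consumes:

- MD from (n, mean, SD) per arm, v_i = sd_t²/n_t + sd_c²/n_c;
- RR pooled on the log scale, v_i = 1/a − 1/n_t + 1/c − 1/n_c;
- 0.5 added to all four cells of a trial with a zero cell in exactly one
  arm; trials with zero events in both arms are excluded (they carry no
  relative-effect information under RR);
- normal 95% intervals (±1.96·SE); no small-sample t or Knapp–Hartung
  adjustment.

When only a published effect and 95% CI are available, `pooled_estimate()`
back-computes SE = CI width / 3.92 (log scale for RR).

## 3. Linear partial-value scoring

Each criterion has a best anchor (score 100) and worst anchor (score 0);
effects map linearly between them. The shipped anchors were fixed by
solving s = 100·(x − worst)/(best − worst) against the published
(effect, score) pairs of the dose-group table, which they reproduce
exactly for all 17 printed scores: tender and swollen joint counts
best −5 / worst 0 joints; morning stiffness best −30 / worst 0 minutes;
ESR best −30 / worst 0 mm/h; rheumatoid factor best −30 / worst 0 IU/mL;
every RR criterion best 0 / worst 1 (so s = 100·(1 − RR)). Anchors are
fully configurable in the tree YAML.

**Clamping.** Scores are *not* clamped to [0, 100] by default: the
published duration-group table contains contributions exceeding their
criterion weight (12 > 11.8), which implies scores above 100 occurred in
the source analysis. A `clamp` flag bounds scores when a strictly bounded
scale is preferred.

**Absent criteria.** A criterion with no estimable pooled effect (e.g. an
adverse event never observed in any trial) scores as a zero contribution
while its weight stays in the aggregation denominator. This is the only
convention consistent with the published branch values (risk 48 with one
absent criterion, 39 with two); renormalising the weights over present
criteria would reward missing evidence.

**Weight bookkeeping.** The published benefit weights (11.8 + 11.8 + 11.8
+ 4.9 + 8.8) sum to 49.1 against a printed branch total of 49.00. The
branch value divides by the actual per-branch weight sum, and the overall
combination uses the stated branch weights 49/51; both dose groups then
round to the published benefit value 43 either way. `criteria_tree()`
enforces the bookkeeping to a 0.5-point rounding tolerance.

**Overall combination.** Two modes are exposed because the source tables
normalise differently. `weight_proportional` (default):
overall = (w_B·B + w_R·R)/100, equal to the total contribution sum when
the weights are exact. `mean_of_branches`: the two branch contribution
sums are averaged — the convention under which the published
duration-group contribution columns combine to 41 and 45. The third
duration column is internally inconsistent in the source (its printed
contributions recompute to 36, not the printed 37, under every convention
we tried); the package reports the recomputed value.

**Rounding.** Displayed values round half away from zero
(`round_half_up()`; base R's round-half-even would turn 24.5 into 24, not
the published 25). Internal arithmetic is never rounded.

## 4. Monte Carlo uncertainty propagation

Each iteration draws every present criterion's effect independently —
Normal(effect, SE) on the MD scale, exp(Normal(log effect, SE_log)) for RR
— and propagates it through scoring and aggregation; 3000 iterations by
default, matching the scale of the source analysis. Percentile (2.5th /
97.5th) intervals are reported rather than normal approximations, since
the propagated distribution is skewed by the log-normal RR draws. Those
draws also make the Monte Carlo mean sit slightly below the plug-in
deterministic value (E[RR draw] = RR·exp(SE²/2) > RR); the tests verify
the simulated mean against this analytic expectation rather than against
the deterministic value.

The original analysis names only its simulation tool, not its
distributions; Normal-on-MD / log-Normal-on-RR is the standard assumption
and is documented as this package's own. Under it, the simulated
dose-group superiority probability lands at ≈77% against the published
78.57% — agreement within Monte Carlo and distributional-assumption error,
not an exact reproduction. No prior updating is performed; "Bayesian" in
this literature's description of such simulations is nomenclature for
forward uncertainty propagation.

**Reproducibility and group streams.** All sampling is seeded. Each
group's stream is derived from the base seed plus a stable hash of the
group's own estimates (common random numbers per group identity), so a
group's draws do not depend on which argument slot it occupies. This makes
`compare_groups()` exactly antisymmetric — swapping the groups maps
P(A>B) to 1 − P(A>B) − P(tie) bit-for-bit — at the cost that comparing a
group against an exact copy of itself yields identical streams (all ties);
perturb any estimate infinitesimally to study near-identical alternatives.

## 5. Weight-sweep sensitivity

The benefit-branch weight is swept over [0, 100] (risk = 100 − benefit;
within-branch weights rescale proportionally, which leaves branch values
unchanged). Both alternatives' overall values are linear in the swept
weight, so the crossing point solves a linear equation and is reported
analytically alongside the sweep grid. The ranking is declared *stable*
when no weight within 20 percentage points of the tree's benefit weight
reverses it — the conventional robustness bar for this kind of model. When
the alternatives tie on one branch, the gap is proportional to the other
branch's difference times the swept weight, so the verdict is
sweep-independent by construction.

## 6. Synthetic data generators

The generators produce the structures the pipeline assumes, nothing more:

- `gen_continuous_trials()`: per-trial true effects θ_i ~ Normal(true_md,
  τ²); arm means and SDs are sample statistics of Normal outcomes. Default
  arm sizes 30–80 and outcome SDs 1–3 reflect the small-to-moderate trials
  typical of the RA literature the case study pools.
- `gen_binary_trials()`: control events Binomial(n, control_risk),
  treatment events Binomial(n, min(1, control_risk·RR_i)) with RR_i
  log-normal around true_rr; default control risk 0.1 matches common
  adverse-event rates. Arm sizes 50–150.
- `gen_expert_panel()`: Likert scores as a discretised latent Normal with
  SD 2·(1 − consensus) around per-criterion targets; consensus 1 collapses
  to the rounded target (CV 0), and lower consensus monotonically raises
  the expected CV, which the tests check over replicates.

What they do *not* emulate: correlated outcomes within trials, publication
bias, risk-of-bias heterogeneity, non-normal outcome distributions,
pattern/subgroup structure, or panel behaviours such as anchoring and
attrition across Delphi rounds. Passing the parameter-recovery and
coverage tests (the pooled 95% CI covers a true MD of −2.5 in ≈95% of
2000 replicates of 20 heterogeneous trials) therefore validates the
arithmetic and its calibration under the model's own assumptions, not
robustness to real-data pathologies.

## 7. Problem sizes and degenerate inputs

The test suite runs the case study at its natural size (10 criteria, 3000
Monte Carlo iterations), the coverage study at 2000 replicates × 20
trials, and the Monte Carlo scaling check at 50 replicates per iteration
count — sizes chosen so the full suite completes in well under a minute
while keeping binomial tolerances tight. Degenerate inputs are handled
explicitly: empty criteria, single experts, single trials, all-double-zero
binary sets and zero-width CIs either error with a named condition or
collapse to the exact deterministic answer, never to a silent zero.

## 8. Known limitations

- Anchors and weights are taken as given; no swing-weighting elicitation.
- Criterion draws are independent — no correlation information exists in
  summary-level inputs; correlated benefits/risks would widen or narrow
  the propagated intervals.
- The criteria tree is exactly two levels (benefit/risk over leaf
  criteria).
- Mantel–Haenszel pooling for sparse binary data is not implemented;
  inverse-variance DL is used throughout.
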