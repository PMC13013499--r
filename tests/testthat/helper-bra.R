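# shared builders for small trees and panels

make_panel <- function(scores, criterion_id = "crit", dimension = "importance") {
  data.frame(expert_id = seq_along(scores), criterion_id = criterion_id,
             dimension = dimension, score = scores, stringsAsFactors = FALSE)
}

# a minimal 1-benefit / 1-risk tree; both criteria on the MD scale with
# anchors best -100 / worst 0, so an effect of -x scores x
simple_tree <- function(w_benefit = 49, w_risk = 51) {
  criteria_tree(list(
    criterion("b1", "benefit", w_benefit, "MD", -100, 0),
    criterion("r1", "risk", w_risk, "MD", -100, 0)),
    branch_weight_benefit = w_benefit, branch_weight_risk = w_risk)
}

# degenerate pooled estimate: zero-width CI at `effect`
const_estimate <- function(effect, scale = "MD") {
  pooled_estimate(scale, effect, effect, effect)
}

# independent brute-force Kendall's W: squared deviation of rank sums
# around their mean over the no-tie maximum m^2 (n^3 - n) / 12
kendall_w_bruteforce <- function(rankings) {
  m <- nrow(rankings); n <- ncol(rankings)
  rs <- colSums(rankings)
  sum((rs - mean(rs))^2) / (m^2 * (n^3 - n) / 12)
}
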