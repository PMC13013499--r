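Package: bramcda
Title: Quantitative Benefit-Risk Assessment of Drugs by Multi-Criteria
    Decision Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantitative benefit-risk assessment
    (BRA) of drugs, developed around the worked case of Fuzi (processed
    Aconitum carmichaelii) decoctions in rheumatoid arthritis. Provides
    Delphi panel statistics with threshold-based criterion screening and
    percentage rank weighting, DerSimonian-Laird random-effects pooling of
    two-arm trial summaries (mean differences and risk ratios), linear
    partial-value scoring against best/worst anchors, weighted two-branch
    aggregation into a single benefit-risk value, Monte Carlo uncertainty
    propagation with between-group superiority probabilities, and
    weight-sweep sensitivity analysis. Includes seed-deterministic
    generators for synthetic two-arm trials and expert Likert panels so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
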