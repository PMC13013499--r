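# Two-branch criteria tree for Fuzi-containing decoctions in RA.
# Weights are the Delphi percentage weights; anchors are the best/worst
# expected effects that map to partial-value scores 100 and 0.
branch_weight_benefit: 49
branch_weight_risk: 51
criteria:
  - id: pressure_pain_joints
    branch: benefit
    weight_percent: 11.8
    scale: MD
    anchor_best: -5     # joints
    anchor_worst: 0
  - id: swollen_joints
    branch: benefit
    weight_percent: 11.8
    scale: MD
    anchor_best: -5     # joints
    anchor_worst: 0
  - id: morning_stiffness
    branch: benefit
    weight_percent: 11.8
    scale: MD
    anchor_best: -30    # minutes
    anchor_worst: 0
  - id: esr
    branch: benefit
    weight_percent: 4.9
    scale: MD
    anchor_best: -30    # mm/h
    anchor_worst: 0
  - id: rheumatoid_factor
    branch: benefit
    weight_percent: 8.8
    scale: MD
    anchor_best: -30    # IU/mL
    anchor_worst: 0
  - id: adr_incidence
    branch: risk
    weight_percent: 15.3
    scale: RR
    anchor_best: 0
    anchor_worst: 1
  - id: cardiovascular_adr
    branch: risk
    weight_percent: 11.7
    scale: RR
    anchor_best: 0
    anchor_worst: 1
  - id: hematologic_adr
    branch: risk
    weight_percent: 10.2
    scale: RR
    anchor_best: 0
    anchor_worst: 1
  - id: liver_kidney_adr
    branch: risk
    weight_percent: 8.7
    scale: RR
    anchor_best: 0
    anchor_worst: 1
  - id: allergy_adr
    branch: risk
    weight_percent: 5.1
    scale: RR
    anchor_best: 0
    anchor_worst: 1
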