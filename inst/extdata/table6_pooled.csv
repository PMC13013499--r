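criterion_id,group,scale,effect,ci_low,ci_high
pressure_pain_joints,low_dose,MD,-2.53,-3.22,-1.85
swollen_joints,low_dose,MD,-1.30,-1.62,-0.99
morning_stiffness,low_dose,MD,-14.33,-18.48,-10.18
esr,low_dose,MD,-7.35,-9.49,-5.22
rheumatoid_factor,low_dose,MD,-17.88,-29.22,-6.54
adr_incidence,low_dose,RR,0.42,0.33,0.53
cardiovascular_adr,low_dose,RR,NA,NA,NA
hematologic_adr,low_dose,RR,0.26,0.11,0.61
liver_kidney_adr,low_dose,RR,0.26,0.14,0.51
allergy_adr,low_dose,RR,0.66,0.15,2.96
pressure_pain_joints,high_dose,MD,-2.22,-3.02,-1.43
swollen_joints,high_dose,MD,-1.26,-1.75,-0.76
morning_stiffness,high_dose,MD,-17.29,-22.18,-12.41
esr,high_dose,MD,-6.61,-11.80,-1.43
rheumatoid_factor,high_dose,MD,-17.08,-27.29,-6.86
adr_incidence,high_dose,RR,0.36,0.23,0.55
cardiovascular_adr,high_dose,RR,NA,NA,NA
hematologic_adr,high_dose,RR,0.46,0.10,2.02
liver_kidney_adr,high_dose,RR,0.45,0.15,1.39
allergy_adr,high_dose,RR,NA,NA,NA
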