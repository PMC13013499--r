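criterion_id,branch,dimension,mean,max_score_freq,cv
adr_incidence,risk,importance,4.84,0.86,0.07
adr_incidence,risk,feasibility,4.68,0.77,0.14
cardiovascular_adr,risk,importance,4.76,0.77,0.09
cardiovascular_adr,risk,feasibility,4.38,0.59,0.11
liver_adr,risk,importance,4.29,0.23,0.10
liver_adr,risk,feasibility,4.15,0.32,0.20
kidney_adr,risk,importance,4.29,0.27,0.10
kidney_adr,risk,feasibility,4.23,0.27,0.14
hematologic_adr,risk,importance,4.21,0.27,0.09
hematologic_adr,risk,feasibility,3.75,0.27,0.20
allergy_adr,risk,importance,4.11,0.32,0.21
allergy_adr,risk,feasibility,4.74,0.86,0.13
gastrointestinal_adr,risk,importance,2.27,0,0.26
gastrointestinal_adr,risk,feasibility,4.06,0.18,0.13
reproductive_adr,risk,importance,4.54,0.36,0.13
reproductive_adr,risk,feasibility,2.82,0,0.21
other_adr,risk,importance,1.84,0,0.19
other_adr,risk,feasibility,2.80,0,0.24
total_effective_rate_clinical,benefit,importance,4.00,0,0
total_effective_rate_clinical,benefit,feasibility,2.00,0,0
total_effective_rate_tcm,benefit,importance,4.84,0.86,0.07
total_effective_rate_tcm,benefit,feasibility,1.00,0,0
overall_disease_score_patient,benefit,importance,1.90,0,0.15
overall_disease_score_patient,benefit,feasibility,1.00,0,0
overall_disease_score_physician,benefit,importance,1.00,0,0
overall_disease_score_physician,benefit,feasibility,2.00,0,0
pain_score,benefit,importance,4.00,0,0
pain_score,benefit,feasibility,1.00,0,0
morning_stiffness,benefit,importance,4.19,0.27,0.11
morning_stiffness,benefit,feasibility,4.06,0.23,0.11
swollen_joints,benefit,importance,5.00,1.00,0
swollen_joints,benefit,feasibility,4.29,0.23,0.10
pressure_pain_joints,benefit,importance,4.18,0.27,0.11
pressure_pain_joints,benefit,feasibility,4.53,0.68,0.11
mobility_function_joints,benefit,importance,5.00,1.00,0
mobility_function_joints,benefit,feasibility,3.00,0,0
grip_strength,benefit,importance,1.95,0,0.15
grip_strength,benefit,feasibility,3.00,0,0
joint_xray,benefit,importance,2.94,0,0.13
joint_xray,benefit,feasibility,3.00,0,0
esr,benefit,importance,4.06,0.27,0.11
esr,benefit,feasibility,4.84,0.86,0.07
c_reactive_protein,benefit,importance,3.00,0,0
c_reactive_protein,benefit,feasibility,4.79,0.87,0.10
white_blood_cell_count,benefit,importance,1.05,0,0.20
white_blood_cell_count,benefit,feasibility,4.84,0.86,0.07
platelet_count,benefit,importance,2.00,0,0.18
platelet_count,benefit,feasibility,4.84,0.86,0.07
rheumatoid_factor,benefit,importance,5.00,1.00,0.00
rheumatoid_factor,benefit,feasibility,4.82,0.5,0.11
immunoglobulin,benefit,importance,3.26,0.09,0.19
immunoglobulin,benefit,feasibility,4.79,0.86,0.10
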