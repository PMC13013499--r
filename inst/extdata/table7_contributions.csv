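criterion_id,branch,weight_percent,group,contribution
pressure_pain_joints,benefit,11.8,within_2_months,12
swollen_joints,benefit,11.8,within_2_months,6.9
morning_stiffness,benefit,11.8,within_2_months,13.9
esr,benefit,4.9,within_2_months,1.4
rheumatoid_factor,benefit,8.8,within_2_months,10.0
adr_incidence,risk,15.3,within_2_months,20.1
cardiovascular_adr,risk,11.7,within_2_months,NA
hematologic_adr,risk,10.2,within_2_months,8.0
liver_kidney_adr,risk,8.7,within_2_months,9.3
allergy_adr,risk,5.1,within_2_months,NA
pressure_pain_joints,benefit,11.8,months_2_to_3,12.7
swollen_joints,benefit,11.8,months_2_to_3,6.1
morning_stiffness,benefit,11.8,months_2_to_3,10.6
esr,benefit,4.9,months_2_to_3,2.9
rheumatoid_factor,benefit,8.8,months_2_to_3,10.6
adr_incidence,risk,15.3,months_2_to_3,17.1
cardiovascular_adr,risk,11.7,months_2_to_3,NA
hematologic_adr,risk,10.2,months_2_to_3,14.2
liver_kidney_adr,risk,8.7,months_2_to_3,11.6
allergy_adr,risk,5.1,months_2_to_3,3.4
pressure_pain_joints,benefit,11.8,over_3_months,4.3
swollen_joints,benefit,11.8,over_3_months,3.4
morning_stiffness,benefit,11.8,over_3_months,12.4
esr,benefit,4.9,over_3_months,2.3
rheumatoid_factor,benefit,8.8,over_3_months,NA
adr_incidence,risk,15.3,over_3_months,18.0
cardiovascular_adr,risk,11.7,over_3_months,NA
hematologic_adr,risk,10.2,over_3_months,17.6
liver_kidney_adr,risk,8.7,over_3_months,14.6
allergy_adr,risk,5.1,over_3_months,NA
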