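risk_factor,sex,age_group,category,relative_risk,rr_ci_low,rr_ci_high,prevalence
low_ca_vitd_intake,female,>=50,exposed,1.14,1.03,1.25,84.1%
low_ca_vitd_intake,male,>=50,exposed,1.14,1.03,1.25,93.6%
low_serum_vitd,female,>=65,exposed,1.56,1.12,2.17,42.1%
low_serum_vitd,male,>=65,exposed,1.56,1.12,2.17,52.8%
smoking,female,>=55,exposed,1.36,1.12,1.65,2.6%
smoking,male,>=55,exposed,1.59,1.04,2.43,17.5%
low_physical_activity,female,>=50,exposed,1.70,1.06,2.70,67.1%
low_physical_activity,male,>=50,exposed,1.70,1.06,2.70,65.4%
low_bmi,female,>=50,exposed,1.79,1.23,3.28,7.7%
low_bmi,male,>=50,exposed,1.79,1.23,3.28,13.3%
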