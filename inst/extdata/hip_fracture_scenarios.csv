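scenario,risk_factor,sex,counterfact_prevalence,flag
easy,low_ca_vitd_intake,female,70%,
easy,low_ca_vitd_intake,male,80%,
easy,low_serum_vitd,female,35%,
easy,low_serum_vitd,male,45%,
easy,smoking,female,1%,
easy,smoking,male,12.5%,
easy,low_physical_activity,female,60%,
easy,low_physical_activity,male,60%,
easy,low_bmi,female,5%,
easy,low_bmi,male,10%,
moderate,low_ca_vitd_intake,female,55%,
moderate,low_ca_vitd_intake,male,65%,
moderate,low_serum_vitd,female,25%,
moderate,low_serum_vitd,male,35%,
moderate,smoking,female,0.5%,
moderate,smoking,male,12.8%,imputed_prediction
moderate,low_physical_activity,female,45%,
moderate,low_physical_activity,male,45%,
moderate,low_bmi,female,2.5%,
moderate,low_bmi,male,7%,
difficult,low_ca_vitd_intake,female,40%,
difficult,low_ca_vitd_intake,male,50%,
difficult,low_serum_vitd,female,15%,
difficult,low_serum_vitd,male,25%,
difficult,smoking,female,0.2%,
difficult,smoking,male,5%,
difficult,low_physical_activity,female,30%,
difficult,low_physical_activity,male,30%,
difficult,low_bmi,female,1%,
difficult,low_bmi,male,5%,
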