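scenario,risk_factor,sex,printed_percent,flag,recomputed_percent
easy,low_ca_vitd_intake,female,1.8,,
easy,low_ca_vitd_intake,male,1.7,,
easy,low_serum_vitd,female,3.2,,
easy,low_serum_vitd,male,3.4,,
easy,smoking,female,0.6,,
easy,smoking,male,2.7,,
easy,low_physical_activity,female,3.4,,
easy,low_physical_activity,male,2.6,,
easy,low_bmi,female,2.0,,
easy,low_bmi,male,2.4,,
moderate,low_ca_vitd_intake,female,3.7,erratum,3.6
moderate,low_ca_vitd_intake,male,3.5,,
moderate,low_serum_vitd,female,7.8,erratum,7.7
moderate,low_serum_vitd,male,7.7,,
moderate,smoking,female,0.8,erratum,0.7
moderate,smoking,male,2.5,imputed_prediction,2.5
moderate,low_physical_activity,female,10.5,,
moderate,low_physical_activity,male,9.8,,
moderate,low_bmi,female,3.9,,
moderate,low_bmi,male,4.5,,
difficult,low_ca_vitd_intake,female,5.5,,
difficult,low_ca_vitd_intake,male,5.4,,
difficult,low_serum_vitd,female,12.3,,
difficult,low_serum_vitd,male,12.0,,
difficult,smoking,female,0.9,,
difficult,smoking,male,6.7,,
difficult,low_physical_activity,female,17.7,,
difficult,low_physical_activity,male,17.0,,
difficult,low_bmi,female,5.0,,
difficult,low_bmi,male,5.9,,
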