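field,risk_factor,sex,scenario,printed,used,note
fact_prevalence,low_serum_vitd,female,,41.2%,42.1%,"the input frequency table prints 41.2%; every scenario table and the results narrative use 42.1%, which reproduces all published burden cells, so 42.1% is canonical here"
counterfact_prevalence,smoking,male,moderate,1%,12.8%,"a printed prediction of 1% sits below the difficult target of 5% and would give an 8.8% burden reduction, not the printed 2.5%; the prediction implied by 2.5% (about 12.8%) is stored and the cell flagged"
burden_percent,low_ca_vitd_intake,female,moderate,3.7,3.6,"recomputation from 84.1% -> 55% at RR 1.14 gives 3.6449%, which prints as 3.6"
burden_percent,smoking,female,moderate,0.8,0.7,"recomputation from 2.6% -> 0.5% at RR 1.36 gives 0.7490%, which prints as 0.7"
burden_percent,low_serum_vitd,female,moderate,7.8,7.7,"recomputation from 42.1% -> 25% at RR 1.56 gives 7.7491%, which prints as 7.7; the published 7.8 is consistent with rounding in two steps (7.75 then 7.8)"
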