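impairment,class,observed_cmax_ratio,observed_auc_ratio,predicted_cmax_ratio,predicted_auc_ratio
renal,normal,1.00,1.00,1.00,1.12
renal,mild,1.02,1.30,1.05,1.32
renal,moderate,1.29,1.77,1.28,1.87
renal,severe,0.94,1.27,0.98,1.33
hepatic,normal,1.00,1.00,0.91,1.05
hepatic,CP-A,0.85,1.03,0.76,1.04
hepatic,CP-B,0.93,1.09,0.84,1.13
hepatic,CP-C,NA,NA,0.79,1.86
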