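population,auc_0_inf_ng_h_ml,cmax_ng_ml,dose_reference
chinese_adult,2062,189.5,chinese_adult
chinese_elderly,2933,254,chinese_adult
elderly_renal_mild,3316,NA,chinese_elderly
elderly_renal_moderate,4151,NA,chinese_elderly
elderly_renal_severe,3285,NA,chinese_elderly
elderly_hepatic_cp_a,3051,NA,chinese_elderly
elderly_hepatic_cp_b,3606,NA,chinese_elderly
elderly_hepatic_cp_c,5059,NA,chinese_elderly
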