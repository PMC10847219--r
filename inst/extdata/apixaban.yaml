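# Apixaban compound parameters (packaged fixture).
# Units are embedded in field names. The effective intestinal surface area
# is the model's single middle-out calibrated constant (see the package
# methods vignette for provenance).
name: apixaban
log_p: 2.22
fu: 0.93
mw_g_mol: 459.0
pka_acid: 13.07
peff_cm_min: 9.0e-7
cl_h_l_h: 2.4
f_gfr: 0.18
bp_ratio: 1.0
intestinal_area_cm2: 1.0748e7
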