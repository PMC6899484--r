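# SYNTHETIC fixture: the 10-treatment / 15-design topology of the diabetes
# network (including one three-arm design acar:metf:plac), with made-up
# effect values. Intended for structural checks (design-matrix shape,
# degrees of freedom, eligibility), NOT for reproducing any reported
# statistic. Effects are arbitrary; all standard errors 0.1.
study_id,treat_ref,treat_alt,effect,se,shared_arm_variance
d01_metf_plac,metf,plac,0.80,0.1,
d02_acar_metf_plac,plac,acar,-0.50,0.1,0.005
d02_acar_metf_plac,plac,metf,-0.75,0.1,0.005
d03_piog_plac,piog,plac,0.65,0.1,
d04_metf_piog,metf,piog,0.05,0.1,
d05_piog_rosi,piog,rosi,0.10,0.1,
d06_metf_rosi,metf,rosi,0.07,0.1,
d07_rosi_sulf,rosi,sulf,0.45,0.1,
d08_acar_sulf,acar,sulf,0.20,0.1,
d09_acar_plac,acar,plac,0.55,0.1,
d10_plac_vild,plac,vild,-0.60,0.1,
d11_metf_sulf,metf,sulf,0.40,0.1,
d12_migl_plac,migl,plac,0.50,0.1,
d13_sita_plac,sita,plac,0.57,0.1,
d14_migl_rosi,migl,rosi,0.02,0.1,
d15_benf_plac,benf,plac,0.48,0.1,
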