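# Diabetes network, metformin / sulfonylurea / rosiglitazone treatment loop
# (HbA1c mean differences), design-level pooled estimates.
# Standard errors are square roots of the reported variances
# 0.014, 0.026, 0.021.
study_id,treat_ref,treat_alt,effect,se,shared_arm_variance
pooled_metf_sulf,metf,sulf,-0.370,0.1183215957,
pooled_metf_rosi,metf,rosi,0.073,0.1612451550,
pooled_sulf_rosi,sulf,rosi,1.20,0.1449137675,
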