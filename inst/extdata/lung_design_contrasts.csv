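# Lung cancer network, design-level pooled estimates (log hazard ratios).
# Three pairwise meta-analyses of radiotherapy (RT), RT + sequential
# chemotherapy (SeqCT) and RT + concomitant chemotherapy (ConCT).
# One pooled row per design; effects are alt-minus-ref.
study_id,treat_ref,treat_alt,effect,se,shared_arm_variance
pooled_RT_SeqCT,RT,SeqCT,-0.132,0.036,
pooled_RT_ConCT,RT,ConCT,-0.138,0.039,
pooled_SeqCT_ConCT,SeqCT,ConCT,-0.179,0.062,
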