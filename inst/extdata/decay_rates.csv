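basis,proliferation,exclusion,species,k_per_year
glm_slope,Yes,No,maple,-1.026
glm_slope,Yes,No,beech,-0.787
glm_slope,Yes,No,mixed,-0.969
glm_slope,No,No,maple,-0.812
glm_slope,No,No,beech,-0.698
glm_slope,No,No,mixed,-0.829
in_mixture,Pooled,No,maple,-1.031
in_mixture,Pooled,No,beech,-0.950
mono_ref,Pooled,No,maple,-0.812
mono_ref,Pooled,No,beech,-0.787
in_mixture,Pooled,Yes,maple,-0.393
mono_ref,Pooled,Yes,maple,-0.248
in_mixture,No,Yes,beech,-0.207
mono_ref,No,Yes,beech,-0.307
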