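alternative,attribute,level
ocs_equivalent,gp_retreatment,5%
ocs_equivalent,hospitalisation,5%
ocs_equivalent,symptom_improvement,100%
ocs_equivalent,pef_improvement,40%
ocs_equivalent,permanent_se,High
ocs_equivalent,temporary_se,High
placebo_equivalent,gp_retreatment,15%
placebo_equivalent,hospitalisation,15%
placebo_equivalent,symptom_improvement,25%
placebo_equivalent,pef_improvement,0%
placebo_equivalent,permanent_se,None
placebo_equivalent,temporary_se,None
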