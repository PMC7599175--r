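outcome,measure,region,field,printed,used,action
motor,FA,FWMR,mean_delayed,1.16,0.16,corrected: FA is unitless in [0;1] by definition; leading digit read as a typo
cognitive,NAA_mI,PWMR,sd_delayed,4.13&1.07),1.07,corrected: malformed punctuation repaired to 4.13(1.07)
cognitive,MD,FWMR,mean_normal,1.14,1.14,suspect (low relative to neighbouring regions; possible digit transposition of 1.41); kept as printed
motor,MD,FWML,mean_normal,1.04,1.04,suspect (low relative to neighbouring regions); kept as printed
motor,NAA_Cho,CWML,sd_normal,0.01,0.01,suspect (implausibly small SD); kept as printed
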