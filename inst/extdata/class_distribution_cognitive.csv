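measure,region,mean_delayed,sd_delayed,mean_normal,sd_normal
NAA_Cho,FWMR,0.64,0.14,0.61,0.10
NAA_Cho,FWML,0.61,0.19,0.61,0.15
NAA_Cho,CWMR,0.82,0.15,0.72,0.14
NAA_Cho,CWML,0.80,0.14,0.72,0.14
NAA_Cho,PWMR,0.89,0.14,0.92,0.23
NAA_Cho,PWML,0.88,0.10,0.92,0.15
NAA_Cr,FWMR,1.47,0.31,1.31,0.36
NAA_Cr,FWML,1.18,0.56,1.29,0.41
NAA_Cr,CWMR,1.42,0.28,1.28,0.22
NAA_Cr,CWML,1.42,0.29,1.28,0.22
NAA_Cr,PWMR,1.56,0.13,1.61,0.43
NAA_Cr,PWML,1.55,0.21,1.59,0.32
Cho_Cr,FWMR,2.32,0.48,2.14,0.44
Cho_Cr,FWML,1.88,0.62,2.13,0.49
Cho_Cr,CWMR,1.75,0.25,1.78,0.13
Cho_Cr,CWML,1.79,0.13,1.78,0.13
Cho_Cr,PWMR,1.76,0.19,1.68,0.44
Cho_Cr,PWML,1.76,0.19,1.74,0.28
NAA_mI,FWMR,2.70,0.77,2.41,0.74
NAA_mI,FWML,2.58,1.20,2.41,0.96
NAA_mI,CWMR,3.82,1.40,3.21,0.94
NAA_mI,CWML,3.82,1.40,3.21,0.94
NAA_mI,PWMR,4.13,1.07,3.71,1.65
NAA_mI,PWML,3.96,0.72,3.92,1.51
mI_Cr,FWMR,0.57,0.16,0.52,0.19
mI_Cr,FWML,0.48,0.19,0.54,0.19
mI_Cr,CWMR,0.36,0.14,0.41,0.08
mI_Cr,CWML,0.36,0.14,0.41,0.08
mI_Cr,PWMR,0.39,0.07,0.37,0.15
mI_Cr,PWML,0.39,0.06,0.36,0.15
MD,FWMR,1.36,0.12,1.14,0.15
MD,FWML,1.35,0.12,1.39,0.15
MD,CWMR,1.31,0.15,1.32,0.15
MD,CWML,1.31,0.20,1.31,0.16
MD,PWMR,1.39,0.22,1.39,0.14
MD,PWML,1.37,0.23,1.36,0.13
FA,FWMR,0.18,0.03,0.16,0.02
FA,FWML,0.17,0.04,0.15,0.02
FA,CWMR,0.23,0.05,0.23,0.04
FA,CWML,0.23,0.07,0.23,0.04
FA,PWMR,0.18,0.05,0.17,0.03
FA,PWML,0.18,0.04,0.17,0.03
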