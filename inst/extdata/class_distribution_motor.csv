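measure,region,mean_delayed,sd_delayed,mean_normal,sd_normal
NAA_Cho,FWMR,0.60,0.12,0.62,0.10
NAA_Cho,FWML,0.66,0.17,0.61,0.14
NAA_Cho,CWMR,0.76,0.15,0.61,0.15
NAA_Cho,CWML,0.77,0.09,0.78,0.01
NAA_Cho,PWMR,0.95,0.22,0.92,0.22
NAA_Cho,PWML,0.87,0.10,0.92,0.16
NAA_Cr,FWMR,1.23,0.31,1.33,0.36
NAA_Cr,FWML,1.29,0.55,1.28,0.40
NAA_Cr,CWMR,1.34,0.25,1.28,0.29
NAA_Cr,CWML,1.39,0.19,1.39,0.21
NAA_Cr,PWMR,1.64,0.33,1.61,0.43
NAA_Cr,PWML,1.55,0.32,1.59,0.32
Cho_Cr,FWMR,2.05,0.39,2.16,0.45
Cho_Cr,FWML,1.93,0.51,2.13,0.49
Cho_Cr,CWMR,1.76,0.21,2.13,0.25
Cho_Cr,CWML,1.81,0.14,1.79,0.25
Cho_Cr,PWMR,1.61,0.39,1.68,0.44
Cho_Cr,PWML,1.74,0.28,1.74,0.28
NAA_mI,FWMR,2.47,0.68,2.44,0.76
NAA_mI,FWML,2.82,0.99,2.37,0.95
NAA_mI,CWMR,3.28,0.89,2.37,1.42
NAA_mI,CWML,3.30,0.53,3.65,1.32
NAA_mI,PWMR,3.79,1.42,3.75,1.64
NAA_mI,PWML,3.89,0.71,3.92,1.53
mI_Cr,FWMR,0.49,0.18,0.53,0.19
mI_Cr,FWML,0.46,0.13,0.55,0.19
mI_Cr,CWMR,0.42,0.08,0.55,0.14
mI_Cr,CWML,0.43,0.05,0.37,0.13
mI_Cr,PWMR,0.37,0.12,0.37,0.15
mI_Cr,PWML,0.41,0.07,0.35,0.15
MD,FWMR,1.33,0.11,1.42,0.15
MD,FWML,1.31,0.11,1.04,0.15
MD,CWMR,1.26,0.16,1.32,0.16
MD,CWML,1.28,0.18,1.32,0.16
MD,PWMR,1.31,0.12,1.40,0.15
MD,PWML,1.34,0.18,1.36,0.13
FA,FWMR,0.16,0.03,0.16,0.02
FA,FWML,0.16,0.03,0.15,0.02
FA,CWMR,0.22,0.04,0.23,0.04
FA,CWML,0.23,0.05,0.23,0.04
FA,PWMR,0.17,0.03,0.17,0.03
FA,PWML,0.17,0.04,0.17,0.03
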