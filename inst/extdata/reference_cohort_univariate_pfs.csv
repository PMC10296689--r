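variable,hr,lcl,ucl,p_value
age_ge65,1.342,0.610,2.952,0.465
sex_female,0.689,0.367,1.292,0.245
smoking_former_current,1.723,0.869,3.418,0.119
stage_iv,1.319,0.317,5.495,0.704
ecog_1_2,1.087,0.573,2.061,0.798
met_brain,1.710,0.902,3.245,0.100
met_bone,1.956,1.045,3.660,0.036
met_liver,1.773,0.862,3.647,0.120
met_adrenal,2.842,0.993,8.132,0.051
met_pleura,1.004,0.490,2.057,0.990
met_contralateral_lung,1.733,0.922,3.255,0.088
pdl1_high,2.532,1.247,5.141,0.010
tki_alectinib,0.397,0.155,1.019,0.055
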