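variable,hr,lcl,ucl,p_value
age_ge65,1.130,0.371,3.444,0.830
sex_female,0.859,0.332,2.219,0.753
smoking_former_current,1.193,0.425,3.349,0.738
stage_iv,0.308,0.068,1.393,0.126
ecog_1_2,5.870,1.344,25.644,0.019
met_brain,1.602,0.616,4.166,0.334
met_bone,2.349,0.901,6.128,0.081
met_liver,2.260,0.835,6.117,0.109
met_adrenal,1.306,0.300,5.688,0.722
met_pleura,0.891,0.293,2.710,0.839
met_contralateral_lung,1.864,0.739,4.699,0.187
pdl1_high,2.945,1.128,7.691,0.027
tki_alectinib,0.275,0.036,2.076,0.211
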