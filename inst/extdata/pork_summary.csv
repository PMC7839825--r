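cut,collection,n,fat_mean,fat_sd,vitd3_mean,vitd3_sd,ohd3_mean,ohd3_sd,vitd2_mean,vitd2_sd,ohd2_mean,ohd2_sd
lean_meat,summer,20,4.2,1.0,0.88,0.25,0.38,0.12,<0.01,,<0.01,
lean_meat,spring,20,4.3,1.1,0.11,0.07,0.11,0.03,<0.01,,<0.01,
sc_fat,summer,20,76.5,4.1,7.27,2.09,0.63,0.13,0.04,0.01,<0.01,
sc_fat,spring,12,83.1,4.4,0.68,0.41,0.21,0.06,0.05,0.03,<0.01,
skin,summer,20,,,7.50,3.28,1.11,0.33,0.02,0.01,<0.01,
skin,spring,12,,,2.28,2.78,0.40,0.21,0.03,0.02,<0.01,
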