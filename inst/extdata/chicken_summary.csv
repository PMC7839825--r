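origin,cut,n,fat_mean,fat_sd,vitd3_mean,vitd3_sd,ohd3_mean,ohd3_sd,vitd2_mean,ohd2_mean
denmark,breast,9,1.4,0.6,0.04,0.02,0.16,0.06,<0.02,<0.01
denmark,thigh_meat,9,6.2,0.9,0.13,0.05,0.28,0.10,<0.02,<0.01
denmark,thigh_with_skin,9,10.8,,0.18,,0.34,,,
denmark,thigh_skin,9,40.8,5.9,0.54,0.24,0.74,0.23,<0.02,<0.01
denmark,minced,1,7.5,,0.10,,0.44,,<0.01,<0.03
france,breast,3,1.1,0.1,0.12,0.06,0.12,0.01,<0.02,<0.01
france,thigh_meat,3,4.4,0.4,0.45,0.18,0.29,0.02,<0.02,<0.01
france,thigh_with_skin,3,9.0,,1.00,,0.36,,,
france,thigh_skin,3,39.1,8.9,4.58,5.68,0.78,0.15,<0.02,<0.01
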