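sample_type,n,fat_pct,vitd3_mean,vitd3_sd,ohd3_mean,ohd3_sd,vitd2_mean,vitd2_sd,ohd2_mean,ohd2_sd
milk_0.5,4,0.5,<0.003,,<0.003,,<0.01,,<0.01,
milk_1.5,4,1.5,0.004,0.001,0.004,0.003,<0.01,,<0.01,
milk_3.5,4,3.5,0.010,0.002,0.007,0.001,<0.01,,<0.01,
milk_organic_3.5,4,3.5,0.008,0.003,0.004,0.002,<0.01,,<0.01,
yoghurt,4,3.5,0.007,0.001,0.007,0.001,<0.01,,<0.01,
cream,4,38,0.119,0.025,0.054,0.007,0.024,0.021,0.021,0.003
butter_spreadable,4,75,0.177,0.032,0.061,0.004,0.016,0.006,0.023,0.006
cheese_hard,4,26,0.051,0.010,0.042,0.008,0.011,0.001,0.014,0.002
cheese_soft,4,30,0.140,0.066,0.053,0.007,0.037,0.014,0.029,0.004
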