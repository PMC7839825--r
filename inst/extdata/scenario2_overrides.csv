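food_id,vitd3,vitd2,ohd3,ohd2
egg_whole,4.0,<0.003,0.5,<0.003
milk_semi_skimmed,0.03,<0.01,0.005,<0.01
milk_whole,0.06,<0.01,0.008,<0.01
yoghurt,0.05,<0.01,0.008,<0.01
cream,0.6,0.024,0.06,0.021
butter_spreadable,1.0,0.016,0.07,0.023
cheese_hard,0.3,0.011,0.05,0.014
chicken_breast,0.3,<0.02,0.18,<0.01
chicken_thigh_with_skin,1.2,<0.02,0.4,<0.01
pork_lean_spring,0.88,<0.01,0.38,<0.01
pork_fat_spring,7.27,0.05,0.63,<0.01
pork_minced_summer,1.39,<0.01,0.40,<0.01
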