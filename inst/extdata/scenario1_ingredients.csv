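food_id,name,group,fat_pct,vitd3,vitd2,ohd3,ohd2,provenance
egg_whole,Whole egg (all hen types),eggs,11,1.34,<0.003,0.43,<0.003,measured
milk_skimmed,Milk 0.5% fat,dairy,0.5,<0.003,<0.01,<0.003,<0.01,measured
milk_semi_skimmed,Milk 1.5% fat,dairy,1.5,0.004,<0.01,0.004,<0.01,measured
milk_whole,Milk 3.5% fat,dairy,3.5,0.010,<0.01,0.007,<0.01,measured
yoghurt,Yoghurt 3.5% fat,dairy,3.5,0.007,<0.01,0.007,<0.01,measured
cream,Cream 38% fat,dairy,38,0.119,0.024,0.054,0.021,measured
butter_spreadable,Spreadable butter 75% fat,dairy,75,0.177,0.016,0.061,0.023,measured
cheese_hard,Hard cheese 26% fat,dairy,26,0.051,0.011,0.042,0.014,measured
cheese_soft,Soft cheese 30% fat,dairy,30,0.140,0.037,0.053,0.029,measured
chicken_breast,Chicken breast without skin,chicken,1.4,0.04,<0.02,0.16,<0.01,measured
chicken_thigh_meat,Chicken thigh meat,chicken,6.2,0.13,<0.02,0.28,<0.01,measured
chicken_thigh_with_skin,Chicken thigh with skin,chicken,10.8,0.18,<0.02,0.34,<0.01,derived
chicken_minced,Minced chicken,chicken,7.5,0.10,<0.01,0.44,<0.03,measured
veal_cut_avg,Veal all-cut average,veal,4.8,0.014,<0.01,0.15,<0.03,derived
calf_liver,Calf liver,veal,3.9,0.047,0.01,0.533,0.07,measured
beef_cut_avg,Beef all-cut average,beef,9.6,0.091,0.035,0.14,0.052,derived
pork_lean_summer,Pork lean meat (summer),pork,4.2,0.88,<0.01,0.38,<0.01,measured
pork_lean_spring,Pork lean meat (early spring),pork,4.3,0.11,<0.01,0.11,<0.01,measured
pork_fat_summer,Pork subcutaneous fat (summer),pork,76.5,7.27,0.04,0.63,<0.01,measured
pork_fat_spring,Pork subcutaneous fat (early spring),pork,83.1,0.68,0.05,0.21,<0.01,measured
pork_minced_summer,Minced pork 10% fat (summer),pork,10,1.39,<0.01,0.40,<0.01,derived
fish_salmon_farmed,Farmed salmon (synthetic stand-in values),fish,12,5.0,<0.05,0.5,<0.05,derived
fish_trout_farmed,Farmed trout (synthetic stand-in values),fish,6,4.0,<0.05,0.4,<0.05,derived
pork_liver,Pork liver (synthetic stand-in values),pork,4,0.5,<0.01,0.3,<0.01,derived
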