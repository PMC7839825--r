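food_id,vitd3,vitd2,ohd3,ohd2
egg_whole,0.30,<0.003,1.30,<0.003
pork_lean_summer,0.10,<0.01,1.00,<0.01
pork_lean_spring,0.08,<0.01,0.90,<0.01
pork_fat_summer,0.70,0.04,2.00,<0.01
pork_fat_spring,0.50,0.05,1.80,<0.01
pork_minced_summer,0.15,<0.01,1.08,<0.01
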