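person_id,age,day,meal_slot,food_ref,amount_g
p001,10,1,breakfast,milk_whole,200
p001,10,1,lunch,omelette,120
p001,10,2,dinner,minced_pork_10pct,90
p001,10,3,breakfast,egg_whole,60
p001,10,4,dinner,chicken_dinner,180
p001,10,6,snack,cheese_hard,30
p002,40,1,breakfast,yoghurt,150
p002,40,2,dinner,pork_minced_summer,150
p002,40,3,lunch,fish_salmon_farmed,100
p002,40,4,dinner,chicken_dinner,250
p002,40,5,breakfast,egg_whole,110
p002,40,7,dinner,beef_cut_avg,160
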