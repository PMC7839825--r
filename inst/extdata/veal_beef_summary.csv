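species,cut,n,fat_mean,fat_sd,vitd3_mean,vitd3_sd,ohd3_mean,ohd3_sd,vitd2_mean,vitd2_sd,ohd2_mean,ohd2_sd
calf,liver,1,3.9,,0.047,,0.533,,0.01,,0.07,
veal,heart_of_rump,6,1.9,0.7,0.011,0.007,0.147,0.055,<0.01,,<0.03,
veal,topside,6,2.0,0.5,<0.01,,0.138,0.060,<0.01,,<0.03,
veal,brisket,6,7.3,4.2,0.020,0.018,0.150,0.086,<0.01,,<0.03,
veal,shortloin,6,8.2,1.9,0.022,0.010,0.153,0.032,<0.01,,<0.03,
beef,topside,6,3.1,1.9,0.064,0.073,0.108,0.073,0.014,0.022,0.036,0.014
beef,heart_of_rump,6,4.2,2.0,0.062,0.022,0.162,0.052,0.027,0.019,0.063,0.034
beef,knuckle,6,7.1,6.1,0.029,0.022,0.110,0.058,0.008,0.006,0.035,0.018
beef,brisket_point_end,6,10.2,4.8,0.036,0.032,0.092,0.034,0.014,0.011,0.025,0.016
beef,brisket_boneless,6,13.1,5.8,0.060,0.079,0.108,0.108,0.022,0.023,0.053,0.045
beef,ribeye,6,13.9,8.3,0.087,0.052,0.140,0.065,0.028,0.024,0.047,0.032
beef,shortloin,6,14.5,4.5,0.173,0.179,0.207,0.098,0.141,0.182,0.103,0.079
beef,minced,6,10.3,1.0,0.220,0.383,0.208,0.044,0.025,0.014,0.050,0.013
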