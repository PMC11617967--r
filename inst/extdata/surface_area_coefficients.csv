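species,mass_min_g,mass_max_g,intercept,coef_mass_g,coef_length_cm,coef_d1_mm,coef_d2_mm,coef_d3_mm,r_squared,n_samples
apple,73,300,61.8323117,1.0484449,0,0,0,0,0.9913,20
white_asparagus,40,85,-6.453975,1.427480,2.917185,0,0,0,0.9888,18
bell_pepper,60,140,57.441,1.9013,0,0,0,0,0.8400,20
carrot,80,160,-4.1316,0.4304613,5.2067765,0.490815,0,0,0.9107,20
radish_tuber,6,12,-14.066,0,0,0,0.57644,0.65288,0.9738,18
plum,34,96,26.5435856,0.63359816,0,0,0,0,0.9529,20
strawberry,7,25,10.6498025,1.862363817,0,0,0,0,0.9237,20
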