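produce,condition,temperature_c,r_tissue_lo_s_cm,r_tissue_hi_s_cm,r_tissue_sd_s_cm,r_boundary_lo_s_cm,r_boundary_hi_s_cm,source
apple_jonagold,individual_free_convection,20,391,391,67,4.8,4.8,measurement
apple_jonagold,individual_free_convection,1,750,750,96,5.2,5.2,measurement
strawberry,fresh_harvest,NA,3,23,NA,NA,NA,literature
plum,fresh_harvest,NA,23,38,NA,NA,NA,literature
radish_tuber,fresh_harvest,NA,0.25,1.5,NA,1.0,1.5,literature
carrot,fresh_harvest,NA,1,6,NA,1.2,2.4,literature
apple,fresh_harvest,NA,170,320,NA,3.0,4.0,literature
white_asparagus,fresh_harvest,NA,11,12.5,NA,1.0,2.0,literature
bell_pepper,fresh_harvest,NA,35,80,NA,3.0,4.5,literature
apple_jonagold_bulk,bulk_box,20,363,363,45,50.4,50.4,measurement
bunch_radishes,perforated_film,NA,NA,NA,NA,18.8,18.8,literature
bunch_radishes,nearly_impermeable_film,NA,NA,NA,NA,820,820,literature
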