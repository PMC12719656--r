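meal_code,serving_g,energy_kcal,fat_g,sat_fat_g,protein_g,total_carb_g,fiber_g,allulose_g
WB20.8,44,106,0.4,0.1,3.7,22.0,1.1,0
WB5.2,11,27,0.1,0.0,0.9,5.5,0.3,0
SirCr,28,140,10,1.0,10,5,2,0
ChdCr,28,140,10,1.5,10,5,2,0
ABBB,40,210,16,3.5,8,12,4,3
PBDCB,40,210,17,4.0,8,11,5,4
ADCB,40,210,17,3.5,8,11,4,3
PBCer,61,247,11,1.5,34,14,2,6
CinnCer,61,247,11,0.8,34,14,2,8
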