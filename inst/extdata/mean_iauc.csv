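meal_code,glucose_iauc,insulin_iauc,n_subjects
WB20.8#1,100.4,228,10
WB20.8#2,121.5,275,10
WB5.2,21.6,50,10
SirCr,8.1,82,10
ChdCr,10.1,96,10
ABBB,7.3,59,10
PBDCB,6.6,64,10
ADCB,2.7,58,10
PBCer,8.0,82,10
CinnCer,4.8,132,10
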