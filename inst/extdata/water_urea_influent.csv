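component,value,unit
Na,3.03,mM
Mg,0.487,mM
Al,0.00015,mM
Si,0.343,mM
K,0.066,mM
Ca,1,mM
Sr,0.00283,mM
Cl,2.63,mM
NO3,0.0181,mM
SO4,0.206,mM
CO3,4.21,mM
NH4,0,mM
Urea,10,mM
O2,0.19,mM
pH,8.23,
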