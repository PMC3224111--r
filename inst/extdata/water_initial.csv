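component,value,unit
Na,3.05,mM
Mg,0.466,mM
Al,0.00028,mM
Si,0.334,mM
K,0.087,mM
Ca,1.05,mM
Sr,0.00282,mM
Cl,2.63,mM
NO3,0.0445,mM
SO4,0.213,mM
CO3,3.23,mM
NH4,0,mM
Urea,1e-07,mM
O2,0.19,mM
pH,7.62,
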