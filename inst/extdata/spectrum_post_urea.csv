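frequency_hz,magnitude_s_per_m,phase_mrad
1,0.0124075,5.4
10,0.0123458,8.1
100,0.0126216,10.3
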