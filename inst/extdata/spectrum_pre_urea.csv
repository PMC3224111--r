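frequency_hz,magnitude_s_per_m,phase_mrad
1,0.0124391,4.1
10,0.0123189,6.9
100,0.0126318,9.5
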