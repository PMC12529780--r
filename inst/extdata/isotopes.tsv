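label	gamma_over_2pi_MHz_per_T
1H	42.577478
2H	6.535902
13C	10.708399
14N	3.077706
15N	-4.317267
31P	17.235162
19F	40.078
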