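substituent,on_state,off_state,ratio,difference,provenance
H,26R,28R,2.35e6,2.35e3,Table 2
H,28M,28R,1.47e6,1.47e3,Table 2
F,26R,28R,8.62e6,8.62e3,Table 2
F,28M,28R,2.09e6,2.09e3,Table 2
CN,26R,28R,1.40,4.65e2,Table 2
CN,28M,28R,1.31,3.68e2,Table 2
NO2,26R,28R,1.44,4.44e2,Table 2
NO2,28M,28R,2.23,1.26e3,Table 2
PhF5,26R,28R,1.71,1.32e3,Table 2
PhF5,28M,28R,0.941,-1.09e2,Table 2
CH3,26R,28R,2.96e7,2.96e4,Table 2
CH3,28M,28R,1.16e6,1.16e3,Table 2
NH2,26R,28R,1.25e1,3.10e4,Table 2
NH2,28M,28R,0.819,-4.90e2,Table 2
OH,26R,28R,2.57e7,2.57e4,Table 2
OH,28M,28R,2.89e6,2.89e3,Table 2
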