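pH,deltaPi,deltaPiErr,deltaPNC,deltaPNCErr,dDelta,dDeltaErr,gammaPi,gammaPNC,dGamma
6,0.58,0.01,0.39,0.01,-0.19,0.02,130,160,30
7,1.34,0.01,1.22,0.01,-0.12,0.02,110,140,30
8,2.32,0.01,2.20,0.01,-0.12,0.02,70,100,30
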