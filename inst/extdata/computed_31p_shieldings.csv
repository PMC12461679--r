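pH,sigmaPi,sigmaPiErr,sigmaPNC,sigmaPNCErr,deltaPi,deltaPiErr,deltaPNC,deltaPNCErr
6,280.9,0.5,278.9,0.4,0.35,0.5,2.38,0.4
7,279.3,0.4,278.7,0.2,1.98,0.4,2.55,0.2
8,278.7,0.3,278.4,0.3,2.63,0.3,2.84,0.3
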