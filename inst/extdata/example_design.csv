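case,PI_deg,SS_deg,slip_pct
1,52,45,30
2,60,50,30
3,68,55,30
4,75,60,30
5,75,45,80
6,75,60,80
7,75,45,60
8,60,45,80
9,75,60,60
10,60,60,80
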