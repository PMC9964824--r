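duration,n_episodes,type_I,type_II,type_III,type_IV,cv
1,11,0,4,0,7,0.10
2,7,0,5,2,0,0.16
3,3,0,2,0,1,0.10
4,3,0,1,2,0,0.12
5,2,0,2,0,0,0.21
6,2,1,0,1,0,0.10
7,2,1,1,0,0,0.09
8,2,2,0,0,0,0.15
10,2,0,0,2,0,0.16
11,1,0,0,1,0,0.29
13,2,0,0,2,0,0.21
14,1,0,0,1,0,0.25
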