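episode,duration,n_bb_days,impact
4,1,1,High
7,1,1,High
8,5,1,Low
10,10,4,Low
11,1,1,High
15,13,4,Low
16,14,5,Low
18,10,1,Low
19,2,2,High
20,4,1,Low
21,13,4,Low
24,5,2,Low
25,3,2,High
26,3,2,High
27,7,6,High
30,11,2,Low
32,1,1,High
33,2,1,High
37,2,2,High
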