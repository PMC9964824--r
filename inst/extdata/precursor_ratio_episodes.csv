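episode,type,pm25_co_clean,pm25_co_episodic,nox_co_clean,nox_co_episodic,so2_co_clean,so2_co_episodic
1,I,56.5,57.2,55.9,53.1,2.9,2.5
6,II,56.5,63.6,55.9,54.5,2.9,2.7
7,IV,56.5,66.3,55.9,50.6,2.9,3.6
11,IV,56.5,83.8,55.9,52.2,2.9,2.9
12,II,66.4,79.1,59.9,54.5,2.7,4.2
16,III,66.4,83.4,59.9,50.61,2.7,2.5
21,III,52.8,57.1,50.3,48.6,1.7,1.8
22,II,52.8,63.7,50.3,44.8,1.7,1.7
25,IV,56.9,67.2,57.8,46.9,1.8,0.9
26,II,56.9,61.6,57.8,48.6,1.8,1.5
27,I,56.9,66.3,57.8,38.1,1.8,2.3
37,II,47.0,51.7,36.7,31.2,2.1,
38,II,47.0,56.2,36.7,35.9,2.1,
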