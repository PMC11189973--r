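c_soil_i,efficiency_pct,level
10,33,high
9,47,high
8,60,high
7,73,high
6,87,high
5,100,moderate
4,118,moderate
3,136,moderate
2,155,low
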