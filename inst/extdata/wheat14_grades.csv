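Num,grade
1,good
2,poor
3,poor
4,excellent
5,poor
6,good
7,poor
8,excellent
9,excellent
10,good
11,good
12,excellent
13,excellent
14,excellent
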