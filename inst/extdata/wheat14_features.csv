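Num,A,P,C,E,R
1,475830,58,1.7775,1,157.2992
2,408765,71,1.019,1.5385,174.6859
3,391425,67,1.0957,2.3103,201.4539
4,581400,76,1.2649,1.4783,185.8696
5,422280,66,1.2182,1.102,159.5918
6,472770,67,1.3235,1.2766,167.6489
7,229755,67,0.6432,1.1463,119.2294
8,557940,75,1.2464,1.8421,209.7519
9,640815,78,1.3236,1.1017,167.0965
10,577320,67,1.6161,1.0714,171.8214
11,451350,73,1.0643,1.9412,201.1364
12,550035,89,0.8726,2.1714,206.7801
13,555135,83,1.0126,1.875,185.045
14,563550,69,1.4875,1.4,198.7831
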