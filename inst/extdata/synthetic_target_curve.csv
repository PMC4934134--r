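pa,rating
0.1,2.194
0.2,4.758
0.3,5.951
0.4,7.63
0.5,10
0.6,9.533
0.7,10
0.8,8.71
0.9,5.419
1,0
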