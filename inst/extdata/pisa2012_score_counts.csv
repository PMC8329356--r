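score,frequency
0,1552
1,5610
2,7316
3,6223
4,4284
5,2726
6,1468
7,644
8,212
9,57
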