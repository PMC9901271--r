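animal,sire,dam
1,0,0
2,0,0
3,0,0
4,0,1
5,2,0
6,2,0
7,0,3
8,4,0
9,4,5
10,6,5
11,6,7
12,4,7
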