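animal,value,sex
4,5.64,m
5,4.30,f
9,4.32,f
10,5.39,m
11,7.72,f
12,4.36,m
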