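5 5 0.96
10 5 0.56
10 10 1.16
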