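iter,prey1,prey2
1,-0.970,-2.508
2,-1.513,-2.991
3,-2.079,-3.432
4,-2.041,-3.106
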