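iter,l,prey1,prey2
1,0.3333,-1.726,-3.864
2,-0.3333,-0.758,-2.664
3,-1,-0.454,-2.430
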