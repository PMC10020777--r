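agent,x1,x2,f
1,-0.451,1.913,14.476
2,1.983,0.562,12.348
3,1.446,3.449,28.6878
4,3.114,-3.367,27.279
5,1.432,0.488,9.406
6,-0.345,3.451,29.333
7,4.378,-1.046,32.412
8,-2.876,2.345,27.143
9,4.129,-2.491,34.833
10,4.345,-3.554,44.426
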