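agent,x1,x2,f,rank
1,-0.619,-2.527,-3.142,5
2,-0.472,-2.462,-2.671,8
3,-0.520,-2.500,-2.820,7
4,-0.678,-2.617,-3.292,4
5,-0.582,-2.634,-2.955,6
6,-1.493,-2.573,-5.270,1
7,-0.458,-2.443,-2.630,9
8,-0.465,-2.762,-2.416,10
9,-0.749,-2.441,-3.570,2
10,-0.667,-2.511,-3.302,3
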