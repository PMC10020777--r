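agent,x1,x2,f,rank
1,1.977,-1.052,9.841,7
2,-3.308,-3.625,-6.024,1
3,-3.997,-1.440,1.540,4
4,-0.753,-5.000,3.296,5
5,1.432,0.488,9.406,6
6,-1.521,-5.000,-0.334,3
7,-0.3487,-2.967,-1.675,2
8,-2.876,2.345,27.143,9
9,3.847,-3.002,34.046,10
10,2.664,-1.293,15.369,8
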