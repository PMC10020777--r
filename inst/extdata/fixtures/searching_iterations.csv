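iter,agent,is_scout,scout,A,C,x1,x2,f
1,1,0,2,-1.8945,0.568,4.972,3.582,47.014
1,2,1,NA,NA,NA,1.983,0.562,12.348
1,3,0,6,1.766,1.802,-3.997,-1.440,1.540
1,4,0,2,1.987,0.876,-0.753,-5.000,3.296
1,5,0,9,-1.235,0.674,5.000,0.185,37.849
1,6,1,NA,NA,NA,-0.345,3.451,29.333
1,7,0,2,1.832,1.566,-0.3487,-2.967,-1.675
1,8,0,6,-1.566,0.934,3.654,4.826,48.620
1,9,1,NA,NA,NA,4.129,-2.491,34.833
1,10,0,9,1.331,0.778,2.621,-4.642,30.258
2,1,1,NA,NA,NA,4.972,3.582,47.014
2,2,0,1,1.433,1.561,-3.308,-3.625,-6.024
2,3,0,4,-1.421,0.942,3.919,-0.353,26.293
2,4,1,NA,NA,NA,-0.753,-5.000,3.296
2,5,0,10,-1.366,1.691,3.397,5.000,49.349
2,6,0,4,1.278,1.256,-1.521,-5.000,-0.334
2,7,0,1,-1.061,0.072,5.000,5.000,58.00
2,8,0,10,-1.211,1.334,2.812,5.000,47.471
2,9,0,4,-1.088,0.131,3.847,-3.002,34.046
2,10,1,NA,NA,NA,2.621,-4.642,30.258
3,1,0,8,1.433,1.561,1.977,-1.052,9.841
3,2,0,8,1.021,0.464,-1.8948,-1.07,-2.36
3,3,0,7,1.366,0.691,4.366,-0.202,30.909
3,4,0,5,1.278,0.256,1.323,-3.023,8.442
3,5,1,NA,NA,NA,3.397,5.000,49.349
3,6,0,5,1.061,0.872,-1.36,-4.931,0.014
3,7,1,NA,NA,NA,5.000,5.000,58.00
3,8,1,NA,NA,NA,2.812,5.000,47.471
3,9,0,7,1.011,0.934,4.168,-2.756,36.767
3,10,0,7,1.188,0.131,2.664,-1.293,15.369
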