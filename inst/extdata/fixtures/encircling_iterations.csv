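iter,agent,D1,D2,x1,x2,f,d_check
1,1,3.703,2.812,2.482,-0.669,13.556,1
1,2,1.582,0.239,0.072,-3.592,1.943,1
1,3,2.271,2.424,0.855,-1.109,3.182,1
1,4,0.973,1.136,-0.620,-2.573,-3.124,1
1,5,3.158,4.352,1.863,1.082,13.676,1
1,6,0.205,1.136,-1.493,-2.573,-5.270,1
1,7,1.377,0.897,-0.161,-2.845,-1.040,1
1,8,1.150,6.209,-0.419,3.192,26.629,1
1,9,5.573,0.862,4.607,-2.884,43.509,1
1,10,4.390,2.571,3.263,-0.942,20.364,1
2,1,3.240,1.995,1.132,-1.500,4.495,1
2,2,0.830,0.929,-0.274,-2.122,-2.039,1
2,3,1.613,1.554,0.183,-1.757,-0.220,1
2,4,0.138,0.091,-0.678,-2.617,-3.292,1
2,5,2.621,3.745,0.771,-0.479,3.820,1
2,6,0.735,0.091,-0.329,-2.611,-2.037,1
2,7,0.597,0.181,-0.410,-2.558,-2.388,1
2,8,0.339,5.855,-0.560,0.753,6.192,1
2,9,5.365,0.221,2.372,-2.535,15.670,1
2,10,4.021,1.721,1.588,-1.659,7.447,1
3,1,1.586,0.931,-0.619,-2.527,-3.142,1
3,2,0.180,0.308,-0.472,-2.462,-2.671,1
3,3,0.637,0.673,-0.520,-2.500,-2.820,1
3,4,0.224,0.181,-0.477,-2.449,-2.693,0
3,5,1.225,1.952,-0.582,-2.634,-2.955,1
3,6,0.124,0.181,-0.467,-2.449,-2.657,1
3,7,0.044,0.128,-0.458,-2.443,-2.630,1
3,8,0.107,3.183,-0.465,-2.762,-2.416,1
3,9,2.826,0.105,-0.749,-2.441,-3.570,1
3,10,2.042,0.771,-0.667,-2.511,-3.302,1
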