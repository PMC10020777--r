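iter,agent,A,C,cur_x1,cur_x2,x1,x2,f
1,1,0.237,1.689,-0.619,-2.527,-1.211,-2.914,-4.650
1,2,0.582,1.411,-0.472,-2.462,-1.491,-3.136,-5.145
1,3,-0.459,1.872,-0.520,-2.500,-0.375,-1.501,-1.923
1,4,0.099,0.084,-0.678,-2.617,-1.029,-2.747,-4.267
1,5,0.671,1.5,-0.582,-2.634,-1.555,-3.266,-5.169
1,6,0.578,1.903,-1.493,-2.573,-1.173,-3.780,-3.236
1,7,0.296,1.533,-0.458,-2.443,-1.274,-2.923,-4.797
1,8,0.432,1.344,-0.465,-2.762,-1.332,-2.772,-4.986
1,9,0.821,0.638,-0.749,-2.441,-1.077,-3.199,-4.001
1,10,0.761,1.298,-0.667,-2.511,-1.420,-3.075,-5.034
2,1,0.982,0.877,-1.211,-2.914,-1.627,-3.276,-5.308
2,2,0.0933,0.0842,-1.491,-3.136,-1.640,-3.260,-5.350
2,3,0.0441,0.763,-0.375,-1.501,-1.547,-3.026,-5.330
2,4,0.921,0.89,-1.029,-2.747,-1.807,-3.066,-5.753
2,5,0.341,1.2,-1.555,-3.266,-1.602,-3.102,-5.393
2,6,0.982,1.562,-1.173,-3.780,-2.682,-3.867,-6.056
2,7,-0.551,0.0931,-1.274,-2.923,-0.8894,-1.534,-3.134
2,8,0.762,1.236,-1.332,-2.772,-1.923,-3.697,-5.379
2,9,0.782,0.911,-1.077,-3.199,-1.749,-3.362,-5.465
2,10,-0.412,1.114,-1.420,-3.075,-1.404,-2.885,-5.103
3,1,0.093,1.091,-1.627,-3.276,-2.139,-3.475,-5.960
3,2,0.060,0.235,-1.640,-3.260,-2.148,-3.579,-5.877
3,3,-0.099,0.0851,-1.547,-3.026,-1.944,-3.162,-5.906
3,4,0.086,0.209,-1.807,-3.066,-2.197,-3.634,-5.882
3,5,-0.512,0.711,-1.602,-3.102,-2.016,-3.093,-6.009
3,6,0.098,0.404,-2.682,-3.867,-2.260,-3.675,-5.912
3,7,-0.511,0.652,-1.274,-2.923,-2.038,-3.081,-6.033
3,8,0.099,1.568,-1.923,-3.697,-2.212,-3.598,-5.936
3,9,-0.567,0.832,-1.749,-3.362,-2.069,-3.144,-6.053
3,10,0.018,0.554,-1.404,-2.885,-2.084,-3.449,-5.913
4,1,0.094,0.105,-2.139,-3.475,-2.222,-3.402,-6.100
4,2,0.872,1.234,-2.148,-3.579,-2.364,-3.327,-6.243
4,3,0.295,1.701,-1.944,-3.162,-2.492,-3.732,-6.074
4,4,0.796,1.342,-2.197,-3.634,-2.472,-3.532,-6.218
4,5,0.0911,0.013,-2.016,-3.093,-2.222,-3.384,-6.111
4,6,-0.091,1.108,-2.260,-3.675,-2.041,-3.085,-6.035
4,7,0.392,1.233,-2.038,-3.081,-2.229,-3.399,-6.108
4,8,0.116,1.98,-2.212,-3.598,-2.253,-3.402,-6.129
4,9,0.951,0.882,-2.069,-3.144,-2.296,-3.491,-6.113
4,10,0.076,0.087,-2.084,-3.449,-2.186,-3.348,-6.095
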