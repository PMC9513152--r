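"y1","y2","y3"
-1.984264,-2.199198,-0.020134
0.438138,1.640156,-0.094459
-0.7727,-2.443127,-0.740914
-0.70163,-0.603498,0.887323
-0.757918,-0.848885,0.886162
-0.406352,0.428488,-0.4971
-1.130841,-1.150691,-1.072754
-0.311093,-1.180718,-0.454516
-2.25055,-1.472431,1.972483
-1.340305,-0.376004,-2.213089
0.707503,1.231771,-0.440925
1.759034,1.58563,2.007826
-1.154062,-1.917591,0.925228
-3.256854,-1.791432,-0.753306
0.460103,0.591039,-0.47874
0.649379,1.295745,0.586738
0.466989,-0.701601,-0.14663
0.931686,-0.358037,-0.509219
-1.181673,-1.843859,-0.035467
0.245363,-0.698683,-1.14179
0.860904,0.260157,1.837554
-0.400014,2.370825,0.507032
-1.281031,-1.298571,-0.829383
-0.285045,0.550477,-1.132634
0.127288,1.286189,0.992723
-1.932911,-0.788906,0.21037
-1.226292,0.104544,-1.146634
0.078328,0.513962,-0.73314
0.373441,1.728032,1.363559
1.339487,-0.026338,1.717413
-2.244241,-1.117487,0.712234
-0.94811,-0.294405,-0.708314
-0.28172,0.779298,-0.317059
1.252817,1.538688,-0.026551
-0.57453,-0.046074,-0.243863
2.738448,0.294711,1.398471
-0.143728,1.063331,-0.751016
0.698444,2.617363,1.093607
-1.500921,-0.291386,-0.510437
0.210104,-0.178859,1.310167
0.225722,0.454509,-0.41457
-0.059907,0.919036,0.900532
0.407243,-1.548306,0.145229
0.972177,-0.525525,1.484602
2.206483,1.460004,0.023896
-0.528981,0.324508,0.636661
-0.078217,2.011232,0.113357
0.249512,2.084923,0.819673
-0.856019,0.042594,0.549842
-0.113281,-0.410038,-0.578543
-1.612285,-2.492346,0.083951
-0.795973,-0.014891,-0.32419
-0.582806,-1.754563,-0.430066
-1.479128,-0.919773,0.370866
-0.231766,-0.420451,0.607904
0.872117,0.681629,0.240344
-1.346426,-0.784783,-0.976539
-0.523975,-0.607742,-1.983609
-0.631124,-1.869424,1.241271
1.963476,0.594225,0.151834
-3.234975,-2.189024,-1.576003
-0.103082,-0.231358,1.145948
-0.347623,-1.246319,-0.016099
1.345437,0.690217,0.067836
-0.680727,-1.406403,-1.880161
0.872773,0.42655,-0.397616
-0.660591,-0.847085,-0.779261
-0.214966,-2.030206,-1.825264
0.260712,0.601011,0.392124
-1.628844,-0.923849,0.646408
-2.058202,0.245751,-2.968542
-1.395229,0.142979,-1.312572
-1.869818,0.175417,1.051598
0.699037,0.632335,-0.040741
0.314316,0.347374,0.995469
-2.597949,-3.212253,-0.666558
-1.162871,-1.206312,-0.72261
0.908917,1.143687,-0.182845
-1.770607,-0.726422,-1.408355
0.860274,2.797026,1.584842
0.275558,0.430513,0.634947
0.367899,-0.778597,0.584568
-0.223809,0.698593,0.324479
1.498278,-0.125905,0.515599
2.178695,0.900162,1.001517
0.415012,1.291465,0.201528
-1.372291,-0.694727,0.584186
-0.356138,-0.764317,-0.730266
-0.23881,-0.370926,0.190582
-0.480519,0.052695,0.691672
-1.395501,-0.244227,-0.760014
-1.566691,-1.557166,-1.008483
2.215801,-0.256327,-1.07918
-1.153124,-0.884075,-1.376204
3.23941,1.8956,2.125157
-0.378529,-1.714673,-0.603129
1.079161,2.337248,1.391379
1.512471,0.333262,0.252747
-1.033955,-0.51263,-0.018674
1.496645,2.213377,1.168249
-0.10581,0.386504,0.494057
-1.961287,-2.044622,0.67234
-1.494701,-1.25677,-0.77523
-0.725273,-1.277613,-1.096125
-1.366485,-0.235602,-1.846824
-0.017986,0.798903,0.246257
-1.099121,-0.452412,1.020054
0.037735,0.418601,0.137297
-0.642219,-0.353301,0.479013
-2.664674,-1.040577,-0.856245
0.943305,1.007178,0.734371
1.142365,-0.828022,0.414712
-0.23997,-0.996971,1.737938
0.774562,-0.500718,-0.189404
-1.355099,1.013956,-0.326196
-0.332399,-2.047674,-1.147278
-0.359163,-1.075393,2.447069
1.135354,0.092049,1.26224
-0.430503,-1.61731,-1.533759
1.993465,-0.854001,0.484466
1.684618,-0.152039,-0.014738
-0.200604,-0.284812,0.025613
-0.632567,-2.215467,-0.538145
0.084306,0.177029,-0.281048
0.999692,2.079035,0.576573
1.620647,1.660792,0.568354
0.425638,0.046449,-0.308912
-0.152127,1.20007,0.9485
-1.001658,-1.123037,0.011923
2.012573,0.674493,0.913738
-0.669372,-0.320161,-0.344522
-1.546619,-1.686237,-1.235259
0.499674,0.875794,1.27459
0.225538,-0.988924,0.967308
-0.135432,-0.356592,-0.507943
-2.126646,-2.784903,-1.301622
0.742407,0.823355,0.255091
-0.594008,1.204207,-1.322911
-1.659719,-1.393219,-1.367504
-0.797153,-0.592708,-1.177817
1.183097,1.149099,-0.278555
-0.267533,-0.771272,0.190747
1.15268,0.320866,-0.446942
0.535871,-0.757893,-0.422348
-1.015821,0.058556,0.497401
-1.350787,1.037397,0.313106
0.886212,1.407521,1.075053
-2.250052,-1.564767,-1.944183
-0.407096,-0.246108,-1.142404
-1.711849,0.272035,-0.630903
-1.15723,0.14238,-0.415981
1.047257,0.985406,1.061545
1.713671,1.808484,2.10461
2.685339,3.039307,2.392302
-2.65571,-0.432133,-2.561838
-0.096332,-2.034546,-0.973485
1.527187,1.635809,1.550355
1.310762,0.931877,0.455278
-0.900811,-1.097406,0.011406
1.967156,0.161877,-0.722583
-0.582461,-0.880408,0.085781
0.354438,0.748827,1.137188
0.247461,-0.594771,0.113739
0.274144,-0.101795,0.6769
-1.170855,-0.7778,0.267215
1.382325,1.399961,0.342602
0.478005,1.643253,0.534666
-0.20417,-0.517878,0.46904
0.177706,0.360938,-0.544997
1.986426,2.07611,-0.058396
-0.691842,-0.222701,-1.575313
-0.26224,-0.142717,-0.730767
1.915125,0.990402,0.464115
-0.347891,-1.802567,-0.701709
0.487166,1.975641,0.427795
1.164842,-0.430849,-0.325865
0.98609,-0.149361,1.608578
-0.261313,-0.432242,-0.601909
0.737275,-0.146153,1.222138
-0.706883,0.004959,-0.072658
-0.109389,0.36942,1.315164
-1.031402,-0.20953,0.216811
0.567775,-0.606981,0.36952
-0.711245,-0.329434,-1.569387
0.536208,-0.927343,-0.452966
0.613575,1.335278,0.704372
-0.39829,-1.583266,-0.680849
-1.158913,-0.388536,0.192107
1.098757,0.433475,1.593558
-1.17417,-0.499787,-2.068164
0.062491,0.30019,-0.072969
-0.107275,-0.369097,0.14623
0.023303,-0.489887,0.312965
0.974893,0.561059,0.543553
-0.549034,0.923149,-0.177099
-1.991024,-0.443024,0.28253
1.479797,0.93312,-0.588766
1.621941,0.997959,0.09295
1.55976,1.808102,1.691174
0.018963,1.302584,0.734461
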