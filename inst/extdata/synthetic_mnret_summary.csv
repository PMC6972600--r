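dose,covariate,n,mean,sd
0,DO,75,0.2935744,0.1217778
1,DO,75,0.2903241,0.1041593
10,DO,75,0.41114,0.1662234
100,DO,75,1.4382972,0.6890375
0,B6C3F1,10,0.1345391,0.0475645
1,B6C3F1,10,0.1737759,0.0700477
5,B6C3F1,10,0.2313688,0.1178565
10,B6C3F1,10,0.2859272,0.1030276
100,B6C3F1,10,0.8661564,0.2297539
200,B6C3F1,10,1.5146606,0.4814243
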