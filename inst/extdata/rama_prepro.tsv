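phi	psi	score
-180	-180	2.174260088
-160	-180	1.828982690
-140	-180	1.481987414
-120	-180	1.331956928
-100	-180	1.398827585
-80	-180	1.348429488
-60	-180	1.311844322
-40	-180	1.836534075
-20	-180	2.295529028
0	-180	2.332607023
20	-180	2.332985128
40	-180	2.332987893
60	-180	2.332987923
80	-180	2.332987912
100	-180	2.332986854
120	-180	2.332934826
140	-180	2.331530623
160	-180	2.311269947
-180	-160	2.322813040
-160	-160	2.287269158
-140	-160	2.222708346
-120	-160	2.182126333
-100	-160	2.205460865
-80	-160	2.225823360
-60	-160	2.236477242
-40	-160	2.307491805
-20	-160	2.331766309
0	-160	2.332973863
20	-160	2.332987779
40	-160	2.332987922
60	-160	2.332987924
80	-160	2.332987923
100	-160	2.332987865
120	-160	2.332985002
140	-160	2.332907628
160	-160	2.331768087
-180	-140	2.332779898
-160	-140	2.332019797
-140	-140	2.330496560
-120	-140	2.329437726
-100	-140	2.330144926
-80	-140	2.331395844
-60	-140	2.332119903
-40	-140	2.332797488
-20	-140	2.332978269
0	-140	2.332987753
20	-140	2.332987921
40	-140	2.332987924
60	-140	2.332987924
80	-140	2.332987924
100	-140	2.332987922
120	-140	2.332987864
140	-140	2.332986298
160	-140	2.332963202
-180	-120	2.332986374
-160	-120	2.332980707
-140	-120	2.332969325
-120	-120	2.332961398
-100	-120	2.332966936
-80	-120	2.332978282
-60	-120	2.332984927
-40	-120	2.332987420
-20	-120	2.332987893
0	-120	2.332987923
20	-120	2.332987924
40	-120	2.332987924
60	-120	2.332987924
80	-120	2.332987924
100	-120	2.332987924
120	-120	2.332987923
140	-120	2.332987911
160	-120	2.332987739
-180	-100	2.332987919
-160	-100	2.332987904
-140	-100	2.332987872
-120	-100	2.332987738
-100	-100	2.332974165
-80	-100	2.332772530
-60	-100	2.332548077
-40	-100	2.332871153
-20	-100	2.332983897
0	-100	2.332987906
20	-100	2.332987924
40	-100	2.332987924
60	-100	2.332987924
80	-100	2.332987924
100	-100	2.332987924
120	-100	2.332987924
140	-100	2.332987924
160	-100	2.332987923
-180	-80	2.332987924
-160	-80	2.332987924
-140	-80	2.332987840
-120	-80	2.332910503
-100	-80	2.323704880
-80	-80	2.203873658
-60	-80	2.097405767
-40	-80	2.258893879
-20	-80	2.330241637
0	-80	2.332975587
20	-80	2.332987916
40	-80	2.332987924
60	-80	2.332987924
80	-80	2.332987924
100	-80	2.332987924
120	-80	2.332987924
140	-80	2.332987924
160	-80	2.332987924
-180	-60	2.332987924
-160	-60	2.332987923
-140	-60	2.332984389
-120	-60	2.329706474
-100	-60	2.039977539
-80	-60	1.030600316
-60	-60	0.692689094
-40	-60	1.306443289
-20	-60	2.227779388
0	-60	2.332463623
20	-60	2.332987618
40	-60	2.332987923
60	-60	2.332987923
80	-60	2.332987924
100	-60	2.332987924
120	-60	2.332987924
140	-60	2.332987924
160	-60	2.332987924
-180	-40	2.332987924
-160	-40	2.332987922
-140	-40	2.332978579
-120	-40	2.324358746
-100	-40	1.766214757
-80	-40	0.568014164
-60	-40	0.218407682
-40	-40	0.861911648
-20	-40	2.092033645
0	-40	2.331602964
20	-40	2.332987065
40	-40	2.332987270
60	-40	2.332986835
80	-40	2.332987688
100	-40	2.332987917
120	-40	2.332987924
140	-40	2.332987924
160	-40	2.332987924
-180	-20	2.332987924
-160	-20	2.332987923
-140	-20	2.332986387
-120	-20	2.331559165
-100	-20	2.184308486
-80	-20	1.401356836
-60	-20	1.085473224
-40	-20	1.645907027
-20	-20	2.284524520
0	-20	2.332759343
20	-20	2.332923332
40	-20	2.332162174
60	-20	2.331613284
80	-20	2.332690127
100	-20	2.332979548
120	-20	2.332987893
140	-20	2.332987924
160	-20	2.332987924
-180	0	2.332987922
-160	0	2.332987918
-140	0	2.332987894
-120	0	2.332973280
-100	0	2.331221314
-80	0	2.305909905
-60	0	2.279154648
-40	0	2.318126349
-20	0	2.332467919
0	0	2.332878233
20	0	2.322503610
40	0	2.212826467
60	0	2.146350026
80	0	2.286279573
100	0	2.331613284
120	0	2.332982895
140	0	2.332987921
160	0	2.332987923
-180	20	2.332987408
-160	20	2.332985521
-140	20	2.332981733
-120	20	2.332979085
-100	20	2.332979830
-80	20	2.332967198
-60	20	2.332951069
-40	20	2.332978239
-20	20	2.332984567
0	20	2.330700370
20	20	2.146350026
40	20	1.374457723
60	20	1.149634548
80	20	1.768751118
100	20	2.304425488
120	20	2.332880563
140	20	2.332987869
160	20	2.332987862
-180	40	2.332903336
-160	40	2.332594086
-140	40	2.331973514
-120	40	2.331541774
-100	40	2.331846217
-80	40	2.332488957
-60	40	2.332867271
-40	40	2.332971782
-20	40	2.332978354
0	40	2.326667042
20	40	1.926337341
40	40	0.913633061
60	40	0.670359136
80	40	1.374457723
100	40	2.257444712
120	40	2.332690103
140	40	2.332987121
160	40	2.332977872
-180	60	2.327909344
-160	60	2.309762203
-140	60	2.275189234
-120	60	2.252449662
-100	60	2.268377003
-80	60	2.303723004
-60	60	2.325735547
-40	60	2.332008595
-20	60	2.332912554
0	60	2.330697432
20	60	2.146349980
40	60	1.374457722
60	60	1.149634548
80	60	1.768751118
100	60	2.304425460
120	60	2.332879112
140	60	2.332947997
160	60	2.332381799
-180	80	2.230857916
-160	80	1.972740360
-140	80	1.676096272
-120	80	1.540449651
-100	80	1.632003931
-80	80	1.906078497
-60	80	2.186345439
-40	80	2.309607776
-20	80	2.331287615
0	80	2.332814290
20	80	2.322502157
40	80	2.212826452
60	80	2.146350026
80	80	2.286279566
100	80	2.331612638
120	80	2.332950689
140	80	2.332103517
160	80	2.319703095
-180	100	1.809224342
-160	100	1.201118314
-140	100	0.760614495
-120	100	0.589553249
-100	100	0.702126391
-80	100	1.060198981
-60	100	1.534935157
-40	100	2.069382012
-20	100	2.312740197
0	100	2.332395400
20	100	2.332911268
40	100	2.332162022
60	100	2.331613283
80	100	2.332690068
100	100	2.332974253
120	100	2.332724953
140	100	2.325811092
160	100	2.233611485
-180	120	1.392531523
-160	120	0.687057224
-140	120	0.225193778
-120	120	0.049758616
-100	120	0.157830699
-80	120	0.412307263
-60	120	0.651702142
-40	120	1.338019655
-20	120	2.196988560
0	120	2.330505533
20	120	2.332950327
40	120	2.332986813
60	120	2.332986832
80	120	2.332987511
100	120	2.332972009
120	120	2.332198424
140	120	2.311730407
160	120	2.079411249
-180	140	1.349838465
-160	140	0.638829650
-140	140	0.175895630
-120	140	0.000000000
-100	140	0.091548297
-80	140	0.151331538
-60	140	0.180202428
-40	140	0.857252417
-20	140	2.027446708
0	140	2.328387845
20	140	2.332944048
40	140	2.332987418
60	140	2.332987920
80	140	2.332987728
100	140	2.332970342
120	140	2.332115464
140	140	2.309546369
160	140	2.058918876
-180	160	1.706886558
-160	160	1.064775546
-140	160	0.616225730
-120	160	0.442926850
-100	160	0.517125668
-80	160	0.444788142
-60	160	0.396313962
-40	160	1.052300282
-20	160	2.114962367
0	160	2.330347672
20	160	2.332969107
40	160	2.332987718
60	160	2.332987922
80	160	2.332987844
100	160	2.332980775
120	160	2.332633024
140	160	2.323324343
160	160	2.203035152
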