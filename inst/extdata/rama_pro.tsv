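phi	psi	score
-180	-180	2.450700665
-160	-180	2.450700665
-140	-180	2.450700665
-120	-180	2.450682477
-100	-180	2.409433587
-80	-180	1.382910411
-60	-180	0.846642957
-40	-180	1.787444215
-20	-180	2.444816558
0	-180	2.450699737
20	-180	2.450700665
40	-180	2.450700665
60	-180	2.450700665
80	-180	2.450700665
100	-180	2.450700665
120	-180	2.450700665
140	-180	2.450700665
160	-180	2.450700665
-180	-160	2.450700665
-160	-160	2.450700665
-140	-160	2.450700665
-120	-160	2.450699866
-100	-160	2.448814154
-80	-160	2.308918039
-60	-160	2.093557021
-40	-160	2.393317097
-20	-160	2.450440676
0	-160	2.450700624
20	-160	2.450700665
40	-160	2.450700665
60	-160	2.450700665
80	-160	2.450700665
100	-160	2.450700665
120	-160	2.450700665
140	-160	2.450700665
160	-160	2.450700665
-180	-140	2.450700665
-160	-140	2.450700665
-140	-140	2.450700665
-120	-140	2.450700657
-100	-140	2.450683258
-80	-140	2.449193217
-60	-140	2.445921967
-40	-140	2.450140973
-20	-140	2.450698270
0	-140	2.450700664
20	-140	2.450700665
40	-140	2.450700665
60	-140	2.450700665
80	-140	2.450700665
100	-140	2.450700665
120	-140	2.450700665
140	-140	2.450700665
160	-140	2.450700665
-180	-120	2.450700665
-160	-120	2.450700665
-140	-120	2.450700665
-120	-120	2.450700665
-100	-120	2.450700630
-80	-120	2.450697591
-60	-120	2.450690692
-40	-120	2.450699469
-20	-120	2.450700660
0	-120	2.450700665
20	-120	2.450700665
40	-120	2.450700665
60	-120	2.450700665
80	-120	2.450700665
100	-120	2.450700665
120	-120	2.450700665
140	-120	2.450700665
160	-120	2.450700665
-180	-100	2.450700665
-160	-100	2.450700665
-140	-100	2.450700665
-120	-100	2.450700664
-100	-100	2.450697889
-80	-100	2.450365682
-60	-100	2.449219571
-40	-100	2.450459954
-20	-100	2.450699232
0	-100	2.450700664
20	-100	2.450700665
40	-100	2.450700665
60	-100	2.450700665
80	-100	2.450700665
100	-100	2.450700665
120	-100	2.450700665
140	-100	2.450700665
160	-100	2.450700665
-180	-80	2.450700665
-160	-80	2.450700665
-140	-80	2.450700665
-120	-80	2.450700434
-100	-80	2.449941280
-80	-80	2.366475467
-60	-80	2.153451112
-40	-80	2.388785284
-20	-80	2.450308486
0	-80	2.450700579
20	-80	2.450700665
40	-80	2.450700665
60	-80	2.450700665
80	-80	2.450700665
100	-80	2.450700665
120	-80	2.450700665
140	-80	2.450700665
160	-80	2.450700665
-180	-60	2.450700665
-160	-60	2.450700665
-140	-60	2.450700665
-120	-60	2.450692453
-100	-60	2.424376128
-80	-60	1.441550191
-60	-60	0.752021012
-40	-60	1.581464748
-20	-60	2.436937582
0	-60	2.450697619
20	-60	2.450700665
40	-60	2.450700665
60	-60	2.450700665
80	-60	2.450700665
100	-60	2.450700665
120	-60	2.450700665
140	-60	2.450700665
160	-60	2.450700665
-180	-40	2.450700665
-160	-40	2.450700665
-140	-40	2.450700664
-120	-40	2.450662721
-100	-40	2.339204865
-80	-40	0.731221357
-60	-40	0.000000000
-40	-40	0.890262234
-20	-40	2.390049860
0	-40	2.450686590
20	-40	2.450700665
40	-40	2.450700665
60	-40	2.450700665
80	-40	2.450700665
100	-40	2.450700665
120	-40	2.450700665
140	-40	2.450700665
160	-40	2.450700665
-180	-20	2.450700665
-160	-20	2.450700665
-140	-20	2.450700665
-120	-20	2.450677884
-100	-20	2.380828722
-80	-20	0.975753174
-60	-20	0.252633278
-40	-20	1.130892433
-20	-20	2.413412616
0	-20	2.450692215
20	-20	2.450700665
40	-20	2.450700665
60	-20	2.450700665
80	-20	2.450700665
100	-20	2.450700665
120	-20	2.450700665
140	-20	2.450700665
160	-20	2.450700665
-180	0	2.450700665
-160	0	2.450700665
-140	0	2.450700665
-120	0	2.450698888
-100	0	2.444885273
-80	0	2.010442536
-60	0	1.460143277
-40	0	2.100481108
-20	0	2.447690003
0	0	2.450700006
20	0	2.450700665
40	0	2.450700665
60	0	2.450700665
80	0	2.450700665
100	0	2.450700665
120	0	2.450700665
140	0	2.450700665
160	0	2.450700665
-180	20	2.450700665
-160	20	2.450700665
-140	20	2.450700665
-120	20	2.450700647
-100	20	2.450641390
-80	20	2.443595885
-60	20	2.419989808
-40	20	2.445585636
-20	20	2.450670063
0	20	2.450700658
20	20	2.450700665
40	20	2.450700665
60	20	2.450700665
80	20	2.450700665
100	20	2.450700665
120	20	2.450700665
140	20	2.450700665
160	20	2.450700665
-180	40	2.450700665
-160	40	2.450700665
-140	40	2.450700665
-120	40	2.450700665
-100	40	2.450700587
-80	40	2.450691242
-60	40	2.450658959
-40	40	2.450693895
-20	40	2.450700625
0	40	2.450700665
20	40	2.450700665
40	40	2.450700665
60	40	2.450700665
80	40	2.450700665
100	40	2.450700665
120	40	2.450700665
140	40	2.450700665
160	40	2.450700665
-180	60	2.450700665
-160	60	2.450700665
-140	60	2.450700665
-120	60	2.450700665
-100	60	2.450700631
-80	60	2.450697749
-60	60	2.450691388
-40	60	2.450699583
-20	60	2.450700660
0	60	2.450700665
20	60	2.450700665
40	60	2.450700665
60	60	2.450700665
80	60	2.450700665
100	60	2.450700665
120	60	2.450700665
140	60	2.450700665
160	60	2.450700665
-180	80	2.450700665
-160	80	2.450700665
-140	80	2.450700665
-120	80	2.450700657
-100	80	2.450683258
-80	80	2.449193217
-60	80	2.445921967
-40	80	2.450140973
-20	80	2.450698270
0	80	2.450700664
20	80	2.450700665
40	80	2.450700665
60	80	2.450700665
80	80	2.450700665
100	80	2.450700665
120	80	2.450700665
140	80	2.450700665
160	80	2.450700665
-180	100	2.450700665
-160	100	2.450700665
-140	100	2.450700665
-120	100	2.450699866
-100	100	2.448814154
-80	100	2.308918039
-60	100	2.093557021
-40	100	2.393317097
-20	100	2.450440676
0	100	2.450700624
20	100	2.450700665
40	100	2.450700665
60	100	2.450700665
80	100	2.450700665
100	100	2.450700665
120	100	2.450700665
140	100	2.450700665
160	100	2.450700665
-180	120	2.450700665
-160	120	2.450700665
-140	120	2.450700665
-120	120	2.450682477
-100	120	2.409433587
-80	120	1.382910411
-60	120	0.846642957
-40	120	1.787444215
-20	120	2.444816558
0	120	2.450699737
20	120	2.450700665
40	120	2.450700665
60	120	2.450700665
80	120	2.450700665
100	120	2.450700665
120	120	2.450700665
140	120	2.450700665
160	120	2.450700665
-180	140	2.450700665
-160	140	2.450700665
-140	140	2.450700663
-120	140	2.450613901
-100	140	2.278744955
-80	140	0.650690106
-60	140	0.081632641
-40	140	1.123909853
-20	140	2.423231878
0	140	2.450696236
20	140	2.450700665
40	140	2.450700665
60	140	2.450700665
80	140	2.450700665
100	140	2.450700665
120	140	2.450700665
140	140	2.450700665
160	140	2.450700665
-180	160	2.450700665
-160	160	2.450700665
-140	160	2.450700663
-120	160	2.450613901
-100	160	2.278744955
-80	160	0.650690106
-60	160	0.081632641
-40	160	1.123909853
-20	160	2.423231878
0	160	2.450696236
20	160	2.450700665
40	160	2.450700665
60	160	2.450700665
80	160	2.450700665
100	160	2.450700665
120	160	2.450700665
140	160	2.450700665
160	160	2.450700665
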