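phi	psi	score
-180	-180	2.12007305
-160	-180	1.76533377
-140	-180	1.45155065
-120	-180	1.31920905
-100	-180	1.35231392
-80	-180	1.23799352
-60	-180	1.20101188
-40	-180	1.70101990
-20	-180	2.27068196
0	-180	2.35201441
20	-180	2.35359593
40	-180	2.35361707
60	-180	2.35361749
80	-180	2.35361731
100	-180	2.35360851
120	-180	2.35335698
140	-180	2.34910073
160	-180	2.30830419
-180	-160	2.32927531
-160	-160	2.26749075
-140	-160	2.17644381
-120	-160	2.12522214
-100	-160	2.14427595
-80	-160	2.12608905
-60	-160	2.12531456
-40	-160	2.27501271
-20	-160	2.34787819
0	-160	2.35350728
20	-160	2.35361576
40	-160	2.35361746
60	-160	2.35361750
80	-160	2.35361748
100	-160	2.35361674
120	-160	2.35359566
140	-160	2.35323743
160	-160	2.34965864
-180	-140	2.35270361
-160	-140	2.35018269
-140	-140	2.34588070
-120	-140	2.34312583
-100	-140	2.34462089
-80	-140	2.34631686
-60	-140	2.34778751
-40	-140	2.35196924
-20	-140	2.35350132
0	-140	2.35361476
20	-140	2.35361744
40	-140	2.35361750
60	-140	2.35361750
80	-140	2.35361750
100	-140	2.35361747
120	-140	2.35361670
140	-140	2.35360356
160	-140	2.35347177
-180	-120	2.35360282
-160	-120	2.35356219
-140	-120	2.35349240
-120	-120	2.35344750
-100	-120	2.35347556
-80	-120	2.35352444
-60	-120	2.35355808
-40	-120	2.35360095
-20	-120	2.35361622
0	-120	2.35361746
20	-120	2.35361750
40	-120	2.35361750
60	-120	2.35361750
80	-120	2.35361750
100	-120	2.35361750
120	-120	2.35361748
140	-120	2.35361727
160	-120	2.35361516
-180	-100	2.35361739
-160	-100	2.35361711
-140	-100	2.35361648
-120	-100	2.35359110
-100	-100	2.35262625
-80	-100	2.34551205
-60	-100	2.33969475
-40	-100	2.34853015
-20	-100	2.35322946
0	-100	2.35361132
20	-100	2.35361748
40	-100	2.35361750
60	-100	2.35361750
80	-100	2.35361750
100	-100	2.35361750
120	-100	2.35361750
140	-100	2.35361750
160	-100	2.35361748
-180	-80	2.35361750
-160	-80	2.35361748
-140	-80	2.35360124
-120	-80	2.35057640
-100	-80	2.24609636
-80	-80	1.80805287
-60	-80	1.61088189
-40	-80	1.95092179
-20	-80	2.30871918
0	-80	2.35287053
20	-80	2.35361500
40	-80	2.35361750
60	-80	2.35361750
80	-80	2.35361750
100	-80	2.35361750
120	-80	2.35361750
140	-80	2.35361750
160	-80	2.35361750
-180	-60	2.35361750
-160	-60	2.35361721
-140	-60	2.35336193
-120	-60	2.30782065
-100	-60	1.57222558
-80	-60	0.61928843
-60	-60	0.35245712
-40	-60	0.84443275
-20	-60	1.90005897
0	-60	2.34200047
20	-60	2.35357830
40	-60	2.35361747
60	-60	2.35361750
80	-60	2.35361750
100	-60	2.35361750
120	-60	2.35361750
140	-60	2.35361750
160	-60	2.35361750
-180	-40	2.35361750
-160	-40	2.35361691
-140	-40	2.35309558
-120	-40	2.26415240
-100	-40	1.27164888
-80	-40	0.27016214
-60	-40	0.00000000
-40	-40	0.49992400
-20	-40	1.65829300
0	-40	2.33016784
20	-40	2.35353742
40	-40	2.35361743
60	-40	2.35361748
80	-40	2.35361749
100	-40	2.35361750
120	-40	2.35361750
140	-40	2.35361750
160	-40	2.35361750
-180	-20	2.35361750
-160	-20	2.35361734
-140	-20	2.35347893
-120	-20	2.32827044
-100	-20	1.79687179
-80	-20	0.91242317
-60	-20	0.65092204
-40	-20	1.13032831
-20	-20	2.05949583
0	-20	2.34728604
20	-20	2.35359424
40	-20	2.35356856
60	-20	2.35350549
80	-20	2.35359345
100	-20	2.35361701
120	-20	2.35361750
140	-20	2.35361750
160	-20	2.35361750
-180	0	2.35361739
-160	0	2.35361710
-140	0	2.35361184
-120	0	2.35272059
-100	0	2.31954777
-80	0	2.12451193
-60	0	2.00597101
-40	0	2.19850499
-20	0	2.33999810
0	0	2.35339422
20	0	2.35267484
40	0	2.33111142
60	0	2.30350611
80	0	2.34242655
100	0	2.35338969
120	0	2.35361707
140	0	2.35361750
160	0	2.35361748
-180	20	2.35360282
-160	20	2.35356219
-140	20	2.35349237
-120	20	2.35344358
-100	20	2.35332108
-80	20	2.35224960
-60	20	2.35135314
-40	20	2.35279991
-20	20	2.35355522
0	20	2.35345675
20	20	2.31365800
40	20	1.79909690
60	20	1.48767237
80	20	2.00737109
100	20	2.34366322
120	20	2.35359850
140	20	2.35361727
160	20	2.35361516
-180	40	2.35270361
-160	40	2.35018269
-140	40	2.34588078
-120	40	2.34313874
-100	40	2.34505652
-80	40	2.34940682
-60	40	2.35237429
-40	40	2.35339751
-20	40	2.35359398
0	40	2.35295540
20	40	2.20570072
40	40	1.23297818
60	40	0.84965433
80	40	1.53585059
100	40	2.31365798
120	40	2.35353816
140	40	2.35360354
160	40	2.35347177
-180	60	2.32927531
-160	60	2.26749076
-140	60	2.17644699
-120	60	2.12568325
-100	60	2.16064651
-80	60	2.24967706
-60	60	2.32047129
-40	60	2.34755522
-20	60	2.35297665
0	60	2.35332071
20	60	2.29093099
40	60	1.62883153
60	60	1.28551532
80	60	1.87522767
100	60	2.33773108
120	60	2.35356519
140	60	2.35323742
160	60	2.34965864
-180	80	2.12007305
-160	80	1.76533380
-140	80	1.45156256
-120	80	1.32067775
-100	80	1.40801049
-80	80	1.68541424
-60	80	2.03565823
-40	80	2.27617793
-20	80	2.34532276
0	80	2.35311677
20	80	2.35117517
40	80	2.29755101
60	80	2.23344314
80	80	2.32526866
100	80	2.35302159
120	80	2.35335587
140	80	2.34910073
160	80	2.30830419
-180	100	1.64703741
-160	100	1.08225583
-140	100	0.69652962
-120	100	0.54819477
-100	100	0.64351044
-80	100	0.93747605
-60	100	1.33866191
-40	100	1.89832749
-20	100	2.29382566
0	100	2.35078808
20	100	2.35351244
40	100	2.35341291
60	100	2.35315418
80	100	2.35351702
100	100	2.35356857
120	100	2.35225855
140	100	2.33046804
160	100	2.15243216
-180	120	1.30741073
-160	120	0.69165361
-140	120	0.29363581
-120	120	0.14236881
-100	120	0.22899285
-80	120	0.41942227
-60	120	0.63033880
-40	120	1.24791443
-20	120	2.11935494
0	120	2.34511452
20	120	2.35339041
40	120	2.35361241
60	120	2.35361728
80	120	2.35361525
100	120	2.35351028
120	120	2.35051747
140	120	2.30220881
160	120	1.97508699
-180	140	1.30741073
-160	140	0.69165360
-140	140	0.29363125
-120	140	0.14182769
-100	140	0.20779232
-80	140	0.23469552
-60	140	0.28197821
-40	140	0.88342816
-20	140	1.95180218
0	140	2.34087720
20	140	2.35337807
40	140	2.35361246
60	140	2.35361743
80	140	2.35361528
100	140	2.35351028
120	140	2.35051747
140	140	2.30220881
160	140	1.97508699
-180	160	1.64703741
-160	160	1.08225580
-140	160	0.69651796
-120	160	0.54680615
-100	160	0.58989383
-80	160	0.49213786
-60	160	0.46519563
-40	160	1.04645326
-20	160	2.04535089
0	160	2.34590274
20	160	2.35350664
40	160	2.35361529
60	160	2.35361747
80	160	2.35361653
100	160	2.35357058
120	160	2.35225855
140	160	2.33046804
160	160	2.15243216
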