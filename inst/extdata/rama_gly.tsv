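phi	psi	score
-180	-180	1.7306139e+00
-160	-180	1.4425408e+00
-140	-180	9.9393561e-01
-120	-180	6.8716184e-01
-100	-180	5.8175034e-01
-80	-180	6.8717283e-01
-60	-180	9.9429993e-01
-40	-180	1.4529124e+00
-20	-180	1.8866108e+00
0	-180	2.0471031e+00
20	-180	1.8866108e+00
40	-180	1.4529124e+00
60	-180	9.9429993e-01
80	-180	6.8717283e-01
100	-180	5.8175034e-01
120	-180	6.8716184e-01
140	-180	9.9393561e-01
160	-180	1.4425408e+00
-180	-160	1.7642622e+00
-160	-160	1.7305579e+00
-140	-160	1.3950490e+00
-120	-160	1.1233574e+00
-100	-160	1.0260030e+00
-80	-160	1.1233936e+00
-60	-160	1.3961689e+00
-40	-160	1.7563597e+00
-20	-160	2.0153461e+00
0	-160	2.0554662e+00
20	-160	1.8223967e+00
40	-160	1.3302656e+00
60	-160	8.4887970e-01
80	-160	5.3500802e-01
100	-160	4.2808681e-01
120	-160	5.3500492e-01
140	-160	8.4877538e-01
160	-160	1.3271356e+00
-180	-140	1.8746108e+00
-160	-140	1.9913624e+00
-140	-140	1.8661817e+00
-120	-140	1.7083848e+00
-100	-140	1.6429929e+00
-80	-140	1.7084694e+00
-60	-140	1.8682702e+00
-40	-140	2.0231141e+00
-20	-140	2.0957766e+00
0	-140	2.0800532e+00
20	-140	1.8886221e+00
40	-140	1.4529593e+00
60	-140	9.9430060e-01
80	-140	6.8717284e-01
100	-140	5.8175064e-01
120	-140	6.8717199e-01
140	-140	9.9427242e-01
160	-140	1.4521497e+00
-180	-120	2.0172532e+00
-160	-120	2.0952812e+00
-140	-120	2.0863274e+00
-120	-120	2.0573511e+00
-100	-120	2.0426521e+00
-80	-120	2.0573259e+00
-60	-120	2.0874202e+00
-40	-120	2.1099272e+00
-20	-120	2.1177251e+00
0	-120	2.1060466e+00
20	-120	2.0192135e+00
40	-120	1.7564874e+00
60	-120	1.3961711e+00
80	-120	1.1233936e+00
100	-120	1.0260041e+00
120	-120	1.1233934e+00
140	-120	1.3961644e+00
160	-120	1.7563292e+00
-180	-100	2.0989622e+00
-160	-100	2.1177563e+00
-140	-100	2.1192497e+00
-120	-100	2.1173791e+00
-100	-100	2.1123483e+00
-80	-100	2.0955771e+00
-60	-100	2.0860483e+00
-40	-100	2.1055493e+00
-20	-100	2.1190673e+00
0	-100	2.1183059e+00
20	-100	2.0990904e+00
40	-100	2.0232701e+00
60	-100	1.8682647e+00
80	-100	1.7084579e+00
100	-100	1.6429894e+00
120	-100	1.7084679e+00
140	-100	1.8682733e+00
160	-100	2.0232579e+00
-180	-80	2.1190543e+00
-160	-80	2.1211337e+00
-140	-80	2.1209809e+00
-120	-80	2.1077831e+00
-100	-80	1.9470409e+00
-80	-80	1.5543878e+00
-60	-80	1.4032648e+00
-40	-80	1.6774081e+00
-20	-80	2.0360536e+00
0	-80	2.1176422e+00
20	-80	2.1189856e+00
40	-80	2.1096621e+00
60	-80	2.0858307e+00
80	-80	2.0547189e+00
100	-80	2.0410808e+00
120	-80	2.0570514e+00
140	-80	2.0875389e+00
160	-80	2.1100673e+00
-180	-60	2.1213516e+00
-160	-60	2.1212681e+00
-140	-60	2.1133934e+00
-120	-60	1.9659067e+00
-100	-60	1.2722005e+00
-80	-60	5.7474519e-01
-60	-60	3.8336201e-01
-40	-60	7.7126299e-01
-20	-60	1.6060851e+00
0	-60	2.0883856e+00
20	-60	2.1195281e+00
40	-60	2.1034703e+00
60	-60	2.0461660e+00
80	-60	2.0022804e+00
100	-60	2.0437444e+00
120	-60	2.1004050e+00
140	-60	2.1180798e+00
160	-60	2.1207992e+00
-180	-40	2.1214588e+00
-160	-40	2.1196131e+00
-140	-40	2.0602840e+00
-120	-40	1.5853402e+00
-100	-40	7.5653314e-01
-80	-40	1.4314306e-01
-60	-40	0.0000000e+00
-40	-40	4.1696968e-01
-20	-40	1.3434614e+00
0	-40	2.0549534e+00
20	-40	2.0985132e+00
40	-40	1.9011198e+00
60	-40	1.4976899e+00
80	-40	1.3076590e+00
100	-40	1.4976871e+00
120	-40	1.9010846e+00
140	-40	2.0992099e+00
160	-40	2.1207861e+00
-180	-20	2.1213750e+00
-160	-20	2.1150152e+00
-140	-20	1.9412304e+00
-120	-20	1.1909827e+00
-100	-20	4.5973497e-01
-80	-20	1.0149401e-01
-60	-20	1.5810650e-01
-40	-20	6.7642110e-01
-20	-20	1.5784439e+00
0	-20	2.0834161e+00
20	-20	2.0040009e+00
40	-20	1.4032402e+00
60	-20	7.5676619e-01
80	-20	5.2065082e-01
100	-20	7.5800596e-01
120	-20	1.4055156e+00
140	-20	2.0053105e+00
160	-20	2.1175568e+00
-180	0	2.1213055e+00
-160	0	2.1131986e+00
-140	0	1.9010775e+00
-120	0	1.0968952e+00
-100	0	3.9620586e-01
-80	0	1.4246155e-01
-60	0	3.6484733e-01
-40	0	1.0347903e+00
-20	0	1.8591569e+00
0	0	2.1000775e+00
20	0	1.8591569e+00
40	0	1.0347903e+00
60	0	3.6484733e-01
80	0	1.4246155e-01
100	0	3.9620586e-01
120	0	1.0968952e+00
140	0	1.9010775e+00
160	0	2.1131986e+00
-180	20	2.1213750e+00
-160	20	2.1175568e+00
-140	20	2.0053105e+00
-120	20	1.4055156e+00
-100	20	7.5800596e-01
-80	20	5.2065082e-01
-60	20	7.5676619e-01
-40	20	1.4032402e+00
-20	20	2.0040009e+00
0	20	2.0834161e+00
20	20	1.5784439e+00
40	20	6.7642110e-01
60	20	1.5810650e-01
80	20	1.0149401e-01
100	20	4.5973497e-01
120	20	1.1909827e+00
140	20	1.9412304e+00
160	20	2.1150152e+00
-180	40	2.1214588e+00
-160	40	2.1207861e+00
-140	40	2.0992099e+00
-120	40	1.9010846e+00
-100	40	1.4976871e+00
-80	40	1.3076590e+00
-60	40	1.4976899e+00
-40	40	1.9011198e+00
-20	40	2.0985132e+00
0	40	2.0549534e+00
20	40	1.3434614e+00
40	40	4.1696968e-01
60	40	1.1102230e-16
80	40	1.4314306e-01
100	40	7.5653314e-01
120	40	1.5853402e+00
140	40	2.0602840e+00
160	40	2.1196131e+00
-180	60	2.1213516e+00
-160	60	2.1207992e+00
-140	60	2.1180798e+00
-120	60	2.1004050e+00
-100	60	2.0437444e+00
-80	60	2.0022804e+00
-60	60	2.0461660e+00
-40	60	2.1034703e+00
-20	60	2.1195281e+00
0	60	2.0883856e+00
20	60	1.6060851e+00
40	60	7.7126299e-01
60	60	3.8336201e-01
80	60	5.7474519e-01
100	60	1.2722005e+00
120	60	1.9659067e+00
140	60	2.1133934e+00
160	60	2.1212681e+00
-180	80	2.1190543e+00
-160	80	2.1100673e+00
-140	80	2.0875389e+00
-120	80	2.0570514e+00
-100	80	2.0410808e+00
-80	80	2.0547189e+00
-60	80	2.0858307e+00
-40	80	2.1096621e+00
-20	80	2.1189856e+00
0	80	2.1176422e+00
20	80	2.0360536e+00
40	80	1.6774081e+00
60	80	1.4032648e+00
80	80	1.5543878e+00
100	80	1.9470409e+00
120	80	2.1077831e+00
140	80	2.1209809e+00
160	80	2.1211337e+00
-180	100	2.0989622e+00
-160	100	2.0232579e+00
-140	100	1.8682733e+00
-120	100	1.7084679e+00
-100	100	1.6429894e+00
-80	100	1.7084579e+00
-60	100	1.8682647e+00
-40	100	2.0232701e+00
-20	100	2.0990904e+00
0	100	2.1183059e+00
20	100	2.1190673e+00
40	100	2.1055493e+00
60	100	2.0860483e+00
80	100	2.0955771e+00
100	100	2.1123483e+00
120	100	2.1173791e+00
140	100	2.1192497e+00
160	100	2.1177563e+00
-180	120	2.0172532e+00
-160	120	1.7563292e+00
-140	120	1.3961644e+00
-120	120	1.1233934e+00
-100	120	1.0260041e+00
-80	120	1.1233936e+00
-60	120	1.3961711e+00
-40	120	1.7564874e+00
-20	120	2.0192135e+00
0	120	2.1060466e+00
20	120	2.1177251e+00
40	120	2.1099272e+00
60	120	2.0874202e+00
80	120	2.0573259e+00
100	120	2.0426521e+00
120	120	2.0573511e+00
140	120	2.0863274e+00
160	120	2.0952812e+00
-180	140	1.8746108e+00
-160	140	1.4521497e+00
-140	140	9.9427242e-01
-120	140	6.8717199e-01
-100	140	5.8175064e-01
-80	140	6.8717284e-01
-60	140	9.9430060e-01
-40	140	1.4529593e+00
-20	140	1.8886221e+00
0	140	2.0800532e+00
20	140	2.0957766e+00
40	140	2.0231141e+00
60	140	1.8682702e+00
80	140	1.7084694e+00
100	140	1.6429929e+00
120	140	1.7083848e+00
140	140	1.8661817e+00
160	140	1.9913624e+00
-180	160	1.7642622e+00
-160	160	1.3271356e+00
-140	160	8.4877538e-01
-120	160	5.3500492e-01
-100	160	4.2808681e-01
-80	160	5.3500802e-01
-60	160	8.4887970e-01
-40	160	1.3302656e+00
-20	160	1.8223967e+00
0	160	2.0554662e+00
20	160	2.0153461e+00
40	160	1.7563597e+00
60	160	1.3961689e+00
80	160	1.1233936e+00
100	160	1.0260030e+00
120	160	1.1233574e+00
140	160	1.3950490e+00
160	160	1.7305579e+00
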