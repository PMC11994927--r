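drug,source_ref,regimen,population,quantity,observed,predicted
dapagliflozin,B26,Po 10 mg SAD,normal,AUC,602.00,397.62
dapagliflozin,B26,Po 10 mg SAD,normal,Cmax,177.83,159.92
dapagliflozin,B26,Po 20 mg SAD,normal,AUC,1027.00,937.74
dapagliflozin,B26,Po 20 mg SAD,normal,Cmax,298.00,329.92
dapagliflozin,B26,Po 10 mg MAD,normal,AUC,727.00,637.94
dapagliflozin,B26,Po 10 mg MAD,normal,Cmax,191.00,172.36
dapagliflozin,B26,Po 20 mg MAD,normal,AUC,1225.00,1452.65
dapagliflozin,B26,Po 20 mg MAD,normal,Cmax,305.00,342.67
canagliflozin,B7,Po 300 mg SAD,normal,AUC,17375.00,23123.26
canagliflozin,B7,Po 300 mg SAD,normal,Cmax,2504.00,3537.86
canagliflozin,B6,Po 100 mg SAD,normal,AUC,10680.02,8859.76
canagliflozin,B6,Po 100 mg SAD,normal,Cmax,1128.84,1389.80
canagliflozin,B6,Po 300 mg SAD,normal,AUC,32131.77,29253.71
canagliflozin,B6,Po 300 mg SAD,normal,Cmax,4118.95,4377.42
canagliflozin,B23,Po 25 mg SAD,normal,AUC,1295.00,1496.56
canagliflozin,B23,Po 25 mg SAD,normal,Cmax,248.00,230.28
canagliflozin,B23,Po 100 mg SAD,normal,AUC,5468.00,6455.97
canagliflozin,B23,Po 100 mg SAD,normal,Cmax,1126.00,1180.77
canagliflozin,B23,Po 200 mg SAD,normal,AUC,11991.00,13673.00
canagliflozin,B23,Po 200 mg SAD,normal,Cmax,2304.00,2456.22
canagliflozin,B23,Po 400 mg SAD,normal,AUC,21836.00,29616.77
canagliflozin,B23,Po 400 mg SAD,normal,Cmax,5028.00,5018.00
canagliflozin,B23,Po 25 mg MAD,normal,AUC,1556.00,1877.12
canagliflozin,B23,Po 25 mg MAD,normal,Cmax,263.00,277.96
canagliflozin,B23,Po 100 mg MAD,normal,AUC,6635.00,7853.33
canagliflozin,B23,Po 100 mg MAD,normal,Cmax,1136.00,1313.79
canagliflozin,B23,Po 200 mg MAD,normal,AUC,16716.00,16587.43
canagliflozin,B23,Po 200 mg MAD,normal,Cmax,2688.00,2695.75
canagliflozin,B23,Po 400 mg MAD,normal,AUC,30766.00,36430.92
canagliflozin,B23,Po 400 mg MAD,normal,Cmax,5236.00,5505.95
canagliflozin,B24,Po 100 mg SAD,normal,AUC,6977.50,10710.15
canagliflozin,B24,Po 100 mg SAD,normal,Cmax,1226.33,1097.42
canagliflozin,B24,Po 200 mg SAD,normal,AUC,14500.88,22087.38
canagliflozin,B24,Po 200 mg SAD,normal,Cmax,2133.60,2303.73
ipragliflozin,B45,Po 5 mg SAD,normal,AUC,300.58,382.53
ipragliflozin,B45,Po 5 mg SAD,normal,Cmax,68.47,94.01
ipragliflozin,B45,Po 30 mg SAD,normal,AUC,2145.75,2760.17
ipragliflozin,B45,Po 30 mg SAD,normal,Cmax,354.64,603.34
ipragliflozin,B45,Po 100 mg SAD,normal,AUC,7727.49,6141.09
ipragliflozin,B45,Po 100 mg SAD,normal,Cmax,960.91,1018.76
ipragliflozin,B45,Po 5 mg MAD,normal,AUC,370.78,468.30
ipragliflozin,B45,Po 5 mg MAD,normal,Cmax,74.06,99.39
ipragliflozin,B45,Po 30 mg MAD,normal,AUC,2487.51,2810.78
ipragliflozin,B45,Po 30 mg MAD,normal,Cmax,427.01,627.39
ipragliflozin,B45,Po 100 mg MAD,normal,AUC,8924.35,7063.53
ipragliflozin,B45,Po 100 mg MAD,normal,Cmax,1105.30,1082.73
ipragliflozin,B50,Po 100 mg SAD,normal,AUC,8400.97,7322.62
ipragliflozin,B50,Po 100 mg SAD,normal,Cmax,1198.72,946.81
empagliflozin,B17,Po 50 mg SAD,normal,AUC,9300.00,9352.98
empagliflozin,B17,Po 50 mg SAD,normal,Cmax,1450.00,1297.20
empagliflozin,B43,Po 50 mg SAD,normal,AUC,8580.00,10052.71
empagliflozin,B43,Po 50 mg SAD,normal,Cmax,1110.00,1121.43
empagliflozin,B3,Po 50 mg SAD,normal,AUC,8430.00,8179.91
empagliflozin,B3,Po 50 mg SAD,normal,Cmax,1180.00,1112.63
empagliflozin,B52,Po 25 mg SAD,normal,AUC,10047.02,8894.20
empagliflozin,B52,Po 25 mg SAD,normal,Cmax,1075.50,1006.10
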