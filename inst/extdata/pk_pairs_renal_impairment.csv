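drug,source_ref,regimen,population,quantity,observed,predicted
dapagliflozin,B27,po 50 mg SAD,normal,AUC,2994.78,2865.89
dapagliflozin,B27,po 50 mg SAD,normal,Cmax,584.68,741.12
dapagliflozin,B27,po 50 mg SAD,mild,AUC,4313.79,3466.97
dapagliflozin,B27,po 50 mg SAD,mild,Cmax,782.05,760.95
dapagliflozin,B27,po 50 mg SAD,moderate,AUC,5322.10,3940.57
dapagliflozin,B27,po 50 mg SAD,moderate,Cmax,815.23,731.51
dapagliflozin,B27,po 50 mg SAD,severe,AUC,5204.24,3956.46
dapagliflozin,B27,po 50 mg SAD,severe,Cmax,815.23,589.54
canagliflozin,B7,po 200 mg SAD,normal,AUC,14345.00,19548.51
canagliflozin,B7,po 200 mg SAD,normal,Cmax,1475.00,2335.53
canagliflozin,B7,po 200 mg SAD,mild,AUC,16719.00,23569.21
canagliflozin,B7,po 200 mg SAD,mild,Cmax,1574.00,2607.86
canagliflozin,B7,po 200 mg SAD,moderate,AUC,23311.00,21423.59
canagliflozin,B7,po 200 mg SAD,moderate,Cmax,1773.00,2449.51
canagliflozin,B7,po 200 mg SAD,severe,AUC,21596.00,22050.24
canagliflozin,B7,po 200 mg SAD,severe,Cmax,1834.00,2557.71
canagliflozin,B24,Po 100 mg SAD,moderate,AUC,8355.80,13461.83
canagliflozin,B24,Po 100 mg SAD,moderate,Cmax,1029.58,1214.69
canagliflozin,B24,Po 200 mg SAD,moderate,AUC,16916.42,40351.40
canagliflozin,B24,Po 200 mg SAD,moderate,Cmax,2133.60,2490.23
ipragliflozin,B15,po 50 mg SAD,mild,AUC,4821.00,5400.46
ipragliflozin,B15,po 50 mg SAD,mild,Cmax,1045.00,842.42
ipragliflozin,B15,po 50 mg SAD,moderate,AUC,4482.00,5221.20
ipragliflozin,B15,po 50 mg SAD,moderate,Cmax,1089.00,855.63
ipragliflozin,B15,po 50 mg SAD,severe,AUC,5948.00,5470.78
ipragliflozin,B15,po 50 mg SAD,severe,Cmax,1161.00,869.59
empagliflozin,B40,po 25 mg SAD,normal,AUC,7589.41,8998.65
empagliflozin,B40,po 25 mg SAD,normal,Cmax,1002.54,995.59
empagliflozin,B40,po 25 mg SAD,mild,AUC,9730.00,9411.87
empagliflozin,B40,po 25 mg SAD,mild,Cmax,1030.00,1004.71
empagliflozin,B40,po 25 mg SAD,moderate,AUC,10800.00,10365.59
empagliflozin,B40,po 25 mg SAD,moderate,Cmax,1000.00,973.72
empagliflozin,B40,po 25 mg SAD,severe,AUC,12200.00,11287.72
empagliflozin,B40,po 25 mg SAD,severe,Cmax,1070.00,993.81
empagliflozin,B31,po 50 mg SAD,normal,AUC,11006.07,11134.13
empagliflozin,B31,po 50 mg SAD,normal,Cmax,1178.23,1029.51
empagliflozin,B31,po 50 mg SAD,mild,AUC,13200.81,11484.10
empagliflozin,B31,po 50 mg SAD,mild,Cmax,1353.31,1035.84
empagliflozin,B31,po 50 mg SAD,moderate,AUC,12333.63,11109.49
empagliflozin,B31,po 50 mg SAD,moderate,Cmax,1178.23,1015.86
empagliflozin,B31,po 50 mg SAD,severe,AUC,17700.00,12076.93
empagliflozin,B31,po 50 mg SAD,severe,Cmax,1178.23,1034.50
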