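element,energy_keV,mu_rho_cm2_g
H,0.5,58
H,0.7,22.4
H,1,7.217
H,1.5,2.148
H,2,1.059
H,3,0.5612
H,4,0.4546
H,5,0.4193
H,6,0.4042
H,8,0.3914
H,10,0.3854
H,15,0.3764
C,0.5,9000
C,0.7,4800
C,1,2211
C,1.5,700.2
C,2,302.6
C,3,92.5
C,4,40.3
C,5,21.2
C,6,12.7
C,8,3.8
C,10,2.1
C,15,0.81
N,0.5,12000
N,0.7,6500
N,1,3311
N,1.5,1083
N,2,476
N,3,146
N,4,64
N,5,33.5
N,6,19
N,8,8.09
N,10,4.42
N,15,1.45
O,0.5,1150
O,0.5314,1050
O,0.532,23000
O,0.7,11200
O,0.85,6800
O,1,4576
O,1.5,1545
O,2,695
O,2.5,366
O,3,217.1
O,3.5,140
O,4,93
O,4.5,66
O,5,48
O,6,27.32
O,8,11.63
O,10,5.952
O,15,1.836
Na,0.5,4250
Na,0.7,1714
Na,1,654
Na,1.0716,546
Na,1.0726,4300
Na,1.25,2840
Na,1.5,1721
Na,2,790
Na,2.5,430
Na,3,258
Na,4,115
Na,5,61
Na,6,36.5
Na,8,16.2
Na,10,8.6
Na,15,2.7
Mg,0.5,6200
Mg,0.7,2500
Mg,1,922
Mg,1.3043,470
Mg,1.3057,3700
Mg,1.5,2480
Mg,2,1124
Mg,2.5,610
Mg,3,364
Mg,4,160
Mg,5,84
Mg,6,50
Mg,8,22
Mg,10,11.6
Mg,15,3.6
Si,0.5,8500
Si,0.7,3500
Si,1,1570
Si,1.5,535
Si,1.838,305
Si,1.8398,3192
Si,2,2534
Si,2.5,1373
Si,3,978
Si,4,453
Si,5,245
Si,6,147
Si,8,64.7
Si,10,33.9
Si,15,10.5
P,0.5,9800
P,0.7,4200
P,1,1913
P,1.5,655
P,2,302
P,2.1444,265
P,2.1466,2610
P,2.5,1728
P,3,1150
P,3.5,760
P,4,520
P,4.5,375
P,5,282
P,6,167
P,8,73.2
P,10,38.7
P,15,11.9
S,0.5,11500
S,0.7,5100
S,1,2430
S,1.5,835
S,2,385
S,2.4708,220
S,2.4732,2550
S,3,1520
S,4,700
S,5,384
S,6,229
S,8,101
S,10,53.6
S,15,16.6
Cl,0.5,13000
Cl,0.7,6000
Cl,1,2970
Cl,1.5,1026
Cl,2,475
Cl,2.821,190
Cl,2.8238,2440
Cl,3,2080
Cl,4,957
Cl,5,530
Cl,6,318
Cl,8,142
Cl,10,75.5
Cl,15,23.6
Ca,0.5,22000
Ca,0.7,10800
Ca,1,5624
Ca,1.5,2011
Ca,2,942
Ca,2.5,525
Ca,3,318
Ca,3.5,212
Ca,3.75,177
Ca,4.0361,146
Ca,4.0401,1310
Ca,4.25,1141
Ca,4.5,983
Ca,5,743
Ca,6,455
Ca,8,204
Ca,10,110
Ca,15,35.3
Sr,0.5,16000
Sr,0.7,6800
Sr,1,2690
Sr,1.5,1080
Sr,1.939,480
Sr,1.941,1450
Sr,2.0055,1400
Sr,2.0075,1900
Sr,2.2149,1750
Sr,2.2171,2310
Sr,3,1185
Sr,4,585
Sr,5,330
Sr,6,200
Sr,8,92
Sr,10,50
Sr,15,16.3
Y,0.5,17500
Y,0.7,7400
Y,1,3000
Y,1.5,1200
Y,2.0789,520
Y,2.0811,1560
Y,2.1549,1500
Y,2.1571,2050
Y,2.3708,1900
Y,2.3732,2480
Y,3,1420
Y,4,700
Y,5,395
Y,6,240
Y,8,110
Y,10,60
Y,15,19.6
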