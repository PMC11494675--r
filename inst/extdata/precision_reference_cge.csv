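standard,trait,grand_mean,s_b,cv
4,GP1,0.55178,0.06442,11.67558
4,GP2,0.23598,0.01753,7.42890
4,GP3,2.49692,0.13954,5.58867
4,GP4,1.72242,0.10966,6.36666
4,GP5,0.15861,0.00947,5.97079
4,GP6,0.05235,0.00394,7.53482
4,GP7,0.26006,0.00684,2.62925
4,GP8,2.19150,0.04903,2.23728
4,GP9,0.29275,0.01205,4.11756
4,GP10,0.87814,0.05814,6.62112
4,GP11,0.26257,0.01283,4.88715
4,GP12,10.59108,0.17319,1.63528
4,GP13,2.32325,0.04467,1.92273
4,GP14,0.45787,0.08707,19.01597
4,GP15,17.75626,0.29415,1.65658
4,GP16,0.51105,0.03594,7.03281
4,GP17,0.31855,0.01611,5.05640
4,GP18,2.38132,0.00000,0.00000
4,GP19,0.26259,0.01089,4.14550
4,GP20,0.39808,0.10490,26.35179
4,GP21,19.82180,0.12608,0.63607
4,GP22,11.07802,0.11211,1.01196
4,GP23,4.62238,0.07290,1.57712
4,GP24,0.56735,0.00048,0.08507
4,GP25,0.14153,0.00974,6.88252
4,GP26,18.27007,0.35280,1.93105
4,GP27,1.39572,0.06021,4.31382
4,G0,20.59545,0.32694,1.58746
4,G1,37.97791,0.21225,0.55888
4,G2,19.80732,0.41745,2.10756
4,S,22.01741,0.59528,2.70366
4,B,14.77107,0.11053,0.74828
4,F,95.47815,0.20490,0.21460
5,GP1,0.74127,0.08522,11.49711
5,GP2,0.30312,0.02647,8.73124
5,GP3,1.51147,0.09810,6.49043
5,GP4,1.65465,0.11243,6.79498
5,GP5,0.20889,0.01339,6.41001
5,GP6,0.04635,0.00385,8.30991
5,GP7,0.24067,0.00784,3.25609
5,GP8,1.76788,0.05528,3.12696
5,GP9,0.29028,0.00846,2.91285
5,GP10,0.94231,0.06915,7.33781
5,GP11,0.29301,0.00968,3.30328
5,GP12,6.72031,0.12628,1.87912
5,GP13,2.55097,0.04109,1.61082
5,GP14,0.64710,0.09990,15.43849
5,GP15,23.97806,0.33387,1.39240
5,GP16,0.44443,0.02536,5.70591
5,GP17,0.41783,0.02389,5.71667
5,GP18,3.98728,0.04582,1.14915
5,GP19,0.37449,0.01000,2.66971
5,GP20,0.47931,0.09729,20.29835
5,GP21,20.23916,0.14977,0.74002
5,GP22,11.09889,0.09277,0.83581
5,GP23,5.19449,0.05133,0.98808
5,GP24,0.70239,0.00882,1.25562
5,GP25,0.17065,0.01150,6.74164
5,GP26,13.54469,0.26104,1.92722
5,GP27,1.45005,0.08585,5.92065
5,G0,28.61244,0.38844,1.35758
5,G1,39.43031,0.24477,0.62076
5,G2,15.16539,0.34002,2.24208
5,S,17.27117,0.52706,3.05166
5,B,17.80750,0.27406,1.53904
5,F,94.64096,0.26649,0.28158
6,GP1,0.48855,0.04958,10.14813
6,GP2,0.27190,0.02621,9.63988
6,GP3,1.98800,0.12907,6.49246
6,GP4,1.97909,0.13060,6.59917
6,GP5,0.16456,0.00982,5.97012
6,GP6,0.03578,0.00526,14.70258
6,GP7,0.18830,0.00688,3.65463
6,GP8,1.55040,0.04856,3.13190
6,GP9,0.31241,0.01120,3.58647
6,GP10,0.87949,0.04480,5.09431
6,GP11,0.33641,0.01450,4.31158
6,GP12,7.98962,0.12962,1.62233
6,GP13,3.62573,0.09127,2.51728
6,GP14,0.59084,0.10994,18.60684
6,GP15,21.22035,0.28272,1.33231
6,GP16,0.47958,0.03157,6.58276
6,GP17,0.35701,0.02405,6.73661
6,GP18,3.64434,0.03545,0.97280
6,GP19,0.35736,0.01024,2.86464
6,GP20,0.39616,0.10016,25.28209
6,GP21,17.56454,0.12850,0.73156
6,GP22,11.33187,0.06913,0.61009
6,GP23,5.28527,0.06120,1.15787
6,GP24,0.76960,0.01297,1.68553
6,GP25,0.21029,0.01482,7.04591
6,GP26,15.89903,0.28134,1.76955
6,GP27,2.08351,0.13019,6.24873
6,G0,25.45553,0.31688,1.24485
6,G1,36.93758,0.23800,0.64434
6,G2,18.19282,0.40259,2.21291
6,S,19.81023,0.56217,2.83779
6,B,19.55050,0.33077,1.69189
6,F,95.11966,0.26471,0.27830
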