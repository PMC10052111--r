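sector,metabolite,n,loq,background_gm,background_gsd,exposed_fraction,exposed_gm,exposed_gsd,seed
construction,MDA,48,0.168,0.03467,1.2195,0.8346,0.35534,2.3705,1002
construction,TDA,8,0.35,0.03,1.65,0.01,0.4,1.85,1001
construction,HDA,8,0.496,0.03524,1.7897,0.3714,7.67616,1.3393,1005
motor_vehicle,MDA,54,0.473,0.17169,1.7035,0.2021,0.55248,2.0207,1003
motor_vehicle,TDA,40,0.379,0.11651,1.723,0.0952,0.17307,2.565,1001
motor_vehicle,HDA,43,0.392,0.06717,1.965,0.1817,9.6877,2.2611,1001
polyurethane,MDA,82,0.4,0.13418,2.3072,0.2847,0.48589,2.238,1001
polyurethane,TDA,70,0.324,0.2563,1.0517,1,0.05408,1.0529,1001
polyurethane,HDA,35,0.362,0.15358,1.6841,0.1879,9.89396,2.277,1003
assembly,MDA,177,0.308,0.18193,1.4728,0.6293,0.06633,2.6013,1001
assembly,TDA,98,0.174,0.07969,1.4546,0.0701,0.40378,2.9322,1001
assembly,HDA,92,0.274,0.15059,1.3629,0.1297,1.92128,2.9534,1001
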