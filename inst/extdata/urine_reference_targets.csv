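sector,metabolite,n,n_geq_loq,gm,p50,p95,max
construction,MDA,48,35,0.3,0.4,1.4,4.0
construction,TDA,8,0,NA,NA,NA,NA
construction,HDA,8,3,0.9,NA,NA,135.2
motor_vehicle,MDA,54,10,0.3,NA,1.1,19.6
motor_vehicle,TDA,40,4,0.2,NA,NA,0.3
motor_vehicle,HDA,43,8,0.4,NA,15.7,44.4
polyurethane,MDA,82,24,0.3,NA,1.3,6.8
polyurethane,TDA,70,11,0.2,NA,0.3,10.4
polyurethane,HDA,35,8,0.4,NA,16.6,20.0
assembly,MDA,177,47,0.2,NA,0.5,81.5
assembly,TDA,98,8,0.1,NA,0.3,3.3
assembly,HDA,92,14,0.2,NA,2.8,34.7
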