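sector,total_workers,exposed_low,exposed_high,mean_exposed
construction,25300,2500,9000,5700
motor_vehicle,22000,8100,10600,9300
assembly,14600,1500,1500,1500
furniture,5300,500,1000,800
plastic_products,4000,800,1000,900
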