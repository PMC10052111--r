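# Demonstration pipeline configuration: synthetic registry-like urinary
# data for the four study sectors, reconstructed and assessed against the
# packaged dose-response and workforce tables.
synthetic: true
sectors:
  - sector: construction
    species: [MDI]
  - sector: motor_vehicle
    species: [MDI, HDI]
  - sector: polyurethane
    species: [MDI, TDI, HDI]
  - sector: assembly
    species: [MDI, TDI, HDI]
reconstruction:
  n_mc: 10000
  mh_iterations: 400
  mh_burn_in: 150
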