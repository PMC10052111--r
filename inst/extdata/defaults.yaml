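# Package-wide default constants. Everything here is auditable and can be
# overridden per call; functions read these values only through accessors.

oel_ug_nco_m3:
  short_term_fi: 35        # Finnish short-term (15-min) OEL
  proposed_boel: 10        # proposed EU binding OEL
  proposed_boel_2029: 6    # proposed EU binding OEL from 2029

# Non-occupational urinary diamine background subtracted before
# reverse dosimetry (ug/L).
background_ug_l: 0.2

# Mean urinary creatinine used when a record carries no creatinine value
# (g/L); converts ug/g creatinine <-> ug/L.
creatinine_mean_g_l: 1.36

# Exposure scenario assumed for reverse dosimetry: sub-chronic repeated
# exposure, urine sampled post-shift on the last working day, no RPE.
scenario:
  weeks: 12
  days_per_week: 5
  hours_per_day: 8

# One-compartment linear kinetic parameters per species. These are
# configurable physiological defaults of this package (plausible for
# inhaled diisocyanate vapour metabolised to the urinary diamine), not
# measured constants: absorbed_fraction of inhaled NCO mass, ventilation
# rate at light work (m3/h), apparent urinary-elimination half-life (h),
# fraction of the absorbed dose excreted in urine as the diamine, urine
# flow (L/h), and a lognormal observation-error GSD.
kinetics:
  MDI:
    absorbed_fraction: 0.8
    ventilation_rate: 1.25
    elimination_half_life: 8
    urinary_excretion_fraction: 0.05
    urine_flow: 0.0625
    error_gsd: 1.3
  TDI:
    absorbed_fraction: 0.8
    ventilation_rate: 1.25
    elimination_half_life: 6
    urinary_excretion_fraction: 0.05
    urine_flow: 0.0625
    error_gsd: 1.3

# Log10-log10 regression calibration between airborne HDI and urinary HDA
# (per g creatinine), with its validity ranges.
hdi_calibration:
  slope: 0.4396
  intercept: 0.4612
  air_range: [0.3, 97.7]     # ug HDI/m3
  urine_range: [1.36, 27.7]  # ug HDA/g creatinine

# Reconstruction defaults: Monte Carlo iterations over the urinary-level
# distribution, and Metropolis-Hastings settings for the kinetic inversion.
reconstruction:
  n_mc: 10000
  mh_iterations: 400
  mh_burn_in: 150
  proposal_scale: 0.7
  prior_scale: 100           # half-normal prior scale on air NCO (ug/m3)

# Excess-risk cap (%) applied to the dose-response interpolant.
risk_cap_pct: 7.5

# Default LOQ (ug/L) used by the synthetic urine generator per metabolite.
generator_loq_ug_l: 0.2
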