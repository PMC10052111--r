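# dihia — diisocyanate exposure reconstruction and health impact assessment

Occupational exposure to diisocyanates (MDI, TDI, HDI, IPDI) causes
respiratory sensitisation, occupational asthma and bronchial
hyperresponsiveness (BHR), and no safe threshold can be identified.
Exposure surveillance in this field leans on two imperfect data streams:
breathing-zone air measurements (blind to dermal uptake and to
respirator use) and urinary diamine biomonitoring (MDA, TDA, HDA,
IPDA), which sees all routes but measures internal dose rather than the
air concentration that regulatory dose–response relations are written
in. `dihia` is an R package for occupational hygienists and risk
assessors that closes that gap: it reconstructs equivalent air exposure
from left-censored urinary biomarker data and converts it into excess
BHR risk and case counts per industrial sector.

## What it computes

* **Censoring and units** (`substitute_below_loq`, `convert_di_to_nco`,
  `creatinine_to_volume`, `exceedance_stats`, `summarize_levels`):
  LOQ/2 substitution for values below the limit of quantitation,
  conversion of species-specific air levels to comparable reactive-NCO
  mass, `ug NCO/m3 = ug DI/m3 × (2 × 42.017 / MW)`, creatinine unit
  conversion, and the standard GM/P50/P95/max summaries with strict
  exceedance counting against OELs.
* **Exposure distributions** (`fit_empirical_distribution`,
  `sample_distribution`): a piecewise-linear inverse CDF through the
  empirical quantiles — skewed, censored biomonitoring data defeat any
  single parametric family.
* **Reverse dosimetry** (`reverse_dosimetry_mh`, `hdi_air_from_hda`,
  `reconstruct_sector`): for MDI/TDI, Bayesian Metropolis–Hastings
  inversion of a linear one-compartment kinetic model (lognormal
  observation error, positivity-constrained half-normal prior) under a
  12-week, 5-day, 8-hour exposure scenario with post-shift sampling;
  for HDI, algebraic inversion of the published calibration
  `log10(HDA) = 0.4396 log10(HDI) + 0.4612`. A 0.2 µg/L
  non-occupational background is subtracted first, and 10,000 Monte
  Carlo iterations integrate over the urinary distribution.
* **Dose–response and HIA** (`lookup_rac_band`, `build_spline`,
  `mean_excess_risk`, `excess_cases`, `task_split_scenario`,
  `run_hia`): the banded excess-risk relation (0.1% below 0.025
  µg NCO/m³ up to 5% above 0.67 µg NCO/m³), interpolated by a monotone
  cubic spline capped at 7.5%, averaged over the reconstructed draws
  and multiplied by per-sector exposed-workforce counts.
* **Synthetic registry-like data** (`generate_urine_samples`,
  `table4_like_fixture`): a seeded two-component lognormal mixture
  generator reproducing the heavy censoring and skew of occupational
  biomonitoring registries, with ground truth retained for recovery
  testing — the original registry data are not public.
* **Orchestration** (`run_pipeline`, plus a thin CLI at
  `inst/cli/dihia.R`): data → reconstruction → HIA with an exclusion
  log and a reproducibility manifest.

## Worked example

```r
library(dihia)

# synthetic motor-vehicle-sector HDA biomonitoring (43 records, ~19% >= LOQ)
fixture <- table4_like_fixture("motor_vehicle", metabolites = "HDA")
res <- reconstruct_sector(fixture, "HDI",
                          config = reconstruction_config(n_mc = 2000, seed = 14))
res
#> <reconstruction_result> HDI: GM 1.511, AM 2.802, P95 10.84 ug NCO/m3
#>   (2000 MC draws, 1581 clamped to 0, 43 urine records)

risk <- mean_excess_risk(res$draws)   # 1.18% mean excess BHR risk
excess_cases(9300, risk)              # 109 excess cases in a 9300-worker sector
```

Most sampled urinary levels fall at or below the 0.2 µg/L background
(1581 of 2000 draws clamp to zero air exposure), yet the quantifiable
tail drives a mean excess BHR risk of about 1.2% over a working life —
the signature of these highly skewed exposure distributions. When
different species belong to different tasks, the workforce can be split
instead of double-counted:

```r
task_split_scenario(9300, data.frame(
  fraction = c(2/3, 1/3), analyte = c("HDI", "MDI"),
  risk_pct = c(1.5, 2.6)))
#> $per_task: HDI 6200 workers -> 93 cases; MDI 3100 workers -> 81 cases
#> $combined: 174
```

The full chain over every configured sector:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "dihia"),
             out_dir = "demo_out", seed = 42)
# writes reconstruction.csv, hia.csv, exclusions.csv, manifest.json
```

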