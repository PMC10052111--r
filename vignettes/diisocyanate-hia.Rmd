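---
title: "Reverse dosimetry and health impact assessment for occupational diisocyanate exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse dosimetry and health impact assessment for occupational diisocyanate exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dihia)
```

## The problem

Diisocyanates (MDI, TDI, HDI, IPDI) are respiratory sensitisers used in
polyurethane manufacture, industrial paints, glues and coatings. The
critical occupational health effect is bronchial hyperresponsiveness
(BHR), for which the EU risk-assessment committee published an
excess-risk/air-concentration relation rather than a threshold limit.
Air monitoring outside respirators misses dermal uptake and overstates
exposure of protected workers, so urinary diamine biomonitoring (MDA,
TDA, HDA, IPDA — the hydrolysis products of the respective
diisocyanates) is the more faithful exposure signal. The catch is that
biomonitoring gives internal dose: to use an air-based dose–response it
must be inverted back to an equivalent air concentration. This package
implements that chain end to end:

1. **Censoring and units** — biomonitoring data are heavily
   left-censored; values below the limit of quantitation (LOQ) are
   replaced by LOQ/2. Air levels of different species are made
   comparable by expressing mass as reactive NCO groups:
   `ug NCO/m3 = ug DI/m3 × (2 × 42.017 / MW)`.
2. **Exposure distribution** — per sector, urinary levels are described
   nonparametrically by a piecewise-linear inverse CDF through the
   empirical quantiles (the skew of these data defeats any single
   lognormal).
3. **Reverse dosimetry** — for MDI and TDI, a one-compartment linear
   kinetic model is inverted with a Bayesian Metropolis–Hastings
   sampler; for HDI, the published log10–log10 regression calibration
   between airborne HDI and urinary HDA (per g creatinine) is inverted
   algebraically. A non-occupational background of 0.2 µg/L is
   subtracted first.
4. **Monte Carlo integration** — 10,000 iterations resample the urinary
   distribution, invert each draw, and summarise the reconstructed air
   exposure (GM, AM, P95 in µg NCO/m³).
5. **Health impact** — per-draw excess BHR risks come from the banded
   dose–response (interpolated by a capped monotone spline), are
   averaged, and multiplied by sector workforce counts to give excess
   cases over a 40-year working life.

## The kinetic model and its inversion

The referenced physiologically based kinetic models for MDI and TDI are
not reproduced here; what the inversion actually needs is their
input–output behaviour — first-order absorption and elimination — so the
package implements a one-compartment linear model with an exact
piecewise-exponential solution. During a shift of length $T$ at air
concentration $C$ (µg NCO/m³), the body burden $A$ accumulates at intake
rate $R = f_{abs} \, V \, C$ (µg/h) while eliminating first order with
$k = \ln 2 / t_{1/2}$:

$$A(t+T) = A(t) e^{-kT} + \frac{R}{k}\left(1 - e^{-kT}\right),$$

and between shifts it simply decays. Composing these two maps over the
working pattern (default 12 weeks × 5 days × 8 h, urine sampled
post-shift on the last working day) gives the burden at the sampling
time in closed form; no ODE solver is involved, and the map
$C \mapsto u$ is exactly linear — the property every downstream step
relies on. The urinary concentration is the renal elimination flux over
urine flow: $u = f_{ue} \, k \, A / Q_{urine}$.

The parameter defaults (see `inst/extdata/defaults.yaml`) are
configurable stand-ins chosen to be physiologically plausible rather
than measured constants: absorbed fraction 0.8 for a reactive inhaled
vapour, ventilation 1.25 m³/h (light work, 10 m³ per shift), apparent
urinary half-lives of 8 h (MDI) and 6 h (TDI), 5% of the absorbed dose
excreted as the diamine, urine flow 1.5 L/day, and a lognormal
observation-error GSD of 1.3 (CV ≈ 27%, a realistic combined analytical
and short-term biological variability for urinary diamine assays). With
an 8 h half-life the 12-week schedule is already within 0.1% of its
periodic steady state, so the scenario length is not a sensitive choice.
Because the values are stand-ins, correctness is established by
properties, not by reproducing any particular published sector estimate:
the closed form is tested against naive fine-step Euler integration
(agreement to 0.1%), and the full chain is tested by parameter recovery
on synthetic data.

Inversion is Bayesian: the likelihood takes $\log u_{obs}$ as normal
around $\log(C \cdot u_{unit})$ with $\sigma = \log(\text{error GSD})$,
and the prior on $C$ is half-normal with a large scale (default 100
µg NCO/m³) — weakly informative, but constraining the reconstructed
exposure to be positive. The Metropolis–Hastings proposal is a lognormal
random walk (multiplicative, with the Hastings correction), so every
state is positive by construction; the default proposal scale of 0.7
gives acceptance rates in the 20–50% band for the posteriors that arise
here, and chains outside 1–99% acceptance trigger a diagnostic warning.
Because the target is scalar, the sampler can be validated exactly: its
quantiles are compared against a dense-grid trapezoid-normalised
posterior and agree within 3% across the 5th–95th percentile band.

**A bias property worth knowing.** When the Monte Carlo integration
draws one posterior sample per resampled urinary level, the arithmetic
mean of reconstructed exposure is biased upward by roughly
$e^{2\sigma^2}$: the measured level already contains the observation
error (factor $e^{\sigma^2/2}$), and the posterior under an effectively
flat-in-$C$ prior is tilted by a further $e^{3\sigma^2/2}$. At GSD 1.3
this is a 15% effect, comfortably inside the 25% recovery tolerance the
package tests; at GSD 1.5 it would be 39%. This is a property of the
estimator, not a defect of the sampler, and is the reason the default
observation-error GSD matters.

## The HDI calibration

No kinetic model is used for HDI; instead the published regression
$\log_{10}(\mathrm{HDA}) = 0.4396 \, \log_{10}(\mathrm{HDI}) + 0.4612$
is inverted algebraically. Its validity ranges (0.3–97.7 µg HDI/m³;
1.36–27.7 µg HDA/g creatinine) are enforced softly: results outside
them carry an `extrapolated` flag rather than being refused, since
censored-data pipelines routinely pass small values through. The
calibration is expressed per gram creatinine, so per-litre urinary
levels are divided by the record's creatinine, or by the packaged mean
of 1.36 g/L when none was measured. Round-tripping the forward and
inverse forms is the identity to 10⁻¹⁰ across the air range.

## The dose–response and its interpolation

The banded excess-risk table spans 0.1% (below 0.025 µg NCO/m³) to 5%
(above 0.67 µg NCO/m³). Two access paths are provided. `lookup_rac_band()`
returns the printed band risk: gaps between bands take the band below,
and the top band is strictly open at 0.67. `build_spline()` interpolates
instead, because averaging over a whole Monte Carlo exposure
distribution calls for a smooth monotone map: knots sit at the band
midpoints (the minimal-assumption summary of a printed range) plus a
(0, 0) anchor, with the open-ended top band represented by its lower
bound; the interpolant is a shape-preserving (Hyman-filtered) cubic, so
risk never decreases with exposure. Above the last knot the curve rises
linearly at the final inter-knot slope until it reaches the 7.5% cap and
is flat thereafter; the cap limits the influence of the few very high
reconstructed exposures on the sector mean, since the table itself ends
at 5%. Note one consequence of the open top band: at exactly
0.67 µg NCO/m³ the band lookup returns 4% while the spline knot reaches
5%; the two paths agree exactly at every closed-band midpoint.

## The synthetic-data generator

The registry data behind the original sector tables are not public, so
the generator emulates their statistical signature: each record is a
non-occupational background level (lognormal) plus, for an exposed
subfraction, an occupational contribution (second lognormal), censored
at the LOQ. A single lognormal cannot jointly reproduce a 10–30%
quantifiable share and max/P95 ratios of an order of magnitude; the
mixture can. The packaged sector fixtures (`table4_like_fixture()`)
freeze mixture parameters that were moment-matched to the published
per-sector summaries (%≥LOQ, GM, P95, with the LOQ itself calibrated
inside each assay's printed LOQ range — several published GM/%≥LOQ
combinations are mutually consistent only at LOQs above 0.2 µg/L), each
with a fixed seed so regeneration is identical. The uncensored truth is
retained in a `true_value` column for recovery scoring; censoring never
alters it.

What the generator deliberately does not emulate: between-worker versus
within-worker variance structure (a single total-variance knob),
temporal trends, correlated co-exposure to several diisocyanates in one
sample, and creatinine–concentration dependence. Passing tests therefore
demonstrate that the chain is self-consistent under realistic skew and
censoring — not that any particular published sector estimate is
reproduced, which the non-public data make impossible by design.

## Numerical choices and problem sizes

* Quantiles everywhere use inclusive-endpoint plotting positions
  $(k-1)/(n-1)$ (`stats::quantile` type 7), so the fitted inverse CDF
  spans exactly the observed range; the convention is configurable, and
  published summary tables cannot adjudicate it without raw data.
* Reported percentages round half away from zero (banker's rounding
  cannot reproduce figures like 81 cases from 80.6).
* Background subtraction floors at zero; zero-clamped draws are counted,
  enter the arithmetic mean as 0, and are excluded from the geometric
  mean (over zeros it is undefined). `gm_include_zeros` switches to a
  floored-GM variant. Because the two means are computed over different
  draw sets, a sector GM can exceed its AM when many draws clamp.
* The sampler-convergence check (empirical quantiles of 10⁵ draws within
  2% of the fitted quantiles on the log scale) is run on a GSD-2 source
  sample: the bound follows from inverse-CDF sampling theory only where
  the fitted curve's local log-slope is modest, and very heavy tails
  (GSD ≥ 3) legitimately exceed it in the extreme quantiles.
* Test and demonstration problem sizes — 10,000 Monte Carlo iterations,
  MH chains of 400 (150 burn-in) per iteration batch, 2 × 10⁵ iterations
  for the grid-oracle comparison — keep the full suite under half a
  minute while leaving the Monte Carlo error well inside every stated
  tolerance; all are configuration values, not code constants.

## Worked example

```{r}
fixture <- table4_like_fixture("motor_vehicle", metabolites = "HDA")
res <- reconstruct_sector(fixture, "HDI",
                          config = reconstruction_config(n_mc = 2000,
                                                         seed = 14))
res
risk <- mean_excess_risk(res$draws)
excess_cases(9300, risk)
```

The pipeline wrapper `run_pipeline()` runs the same chain for every
configured sector and species, writes the reconstruction and HIA tables
plus an exclusion log (pairs with fewer than 5 records or fewer than 2
quantifiable values are excluded, mirroring the sparsity rules such
registries force), and records a manifest (package version, seed, input
digests, timings) that makes any run exactly reproducible.

## Known limitations

* The kinetic stand-in parameters shift reconstructed levels by a
  constant factor (linearity); sector rankings and the recovery
  properties are insensitive to them, absolute levels are not.
* The HDI calibration covers monomeric HDI; exposure to HDI prepolymers
  is not reflected in urinary HDA and will be underestimated.
* Attributing a sector's whole workforce to every species measured in it
  double-counts workers; `task_split_scenario()` exists precisely to
  re-allocate workforce fractions to task-specific species.
* Excess risks are for a 40-year working-life exposure; the package does
  not model risk leveling off after exposure onset, peak exposures, or
  dermal dose–response, none of which the banded relation covers.
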