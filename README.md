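# pawsig

Quantification of plasma-activated water (PAW) induced cytosolic Ca²⁺
signatures from aequorin luminescence.

## What this is for

When plants expressing cytosolic aequorin are challenged with PAW, they
respond with stimulus-specific [Ca²⁺]cyt changes — fast transients for
mildly activated water, sustained elevations for strongly activated water.
Turning the raw plate-reader photon counts into comparable biology requires
a chain of quantitative steps, and `pawsig` implements all of them as
tested, reusable functions:

- **Calibration** of photon counts to molar Ca²⁺ via the aequorin
  rate-constant curve, `pCa = 0.332588·(−log₁₀ k) + 5.5593` with
  `k = (counts/0.5 s) / (total remaining counts)`, closed by the terminal
  discharge that consumes the remaining reporter pool.
- **Signature metrics** per well and per dose epoch: peak, onset delay
  (3-SD crossing with 2-sample persistence), rise slope (OLS onset→peak),
  and the integrated dynamics over 30 or 45 min (trapezoid, no baseline
  subtraction).
- **Thermal dose**: the heat balance `d(m cs T)/dt = Pin − Rcond(T − Tenv)`
  is fitted to water-temperature recordings (decay phase → `Rcond`, heating
  phase → `Pin`), and `E/m = Pin·t_act/m₀` gives the transferred energy per
  unit mass — the dose axis on which different plasma sources are compared.
- **Statistics**: pairwise pooled-variance Student t-tests with a compact
  letter display (groups share a letter iff not significantly different at
  α = 0.05), and dose–response aggregation of mean ± SE integrated signal
  versus energy.
- **A forward simulator** (ground-truth kinetics → Poisson photon counting
  with exact aequorin-pool depletion → noisy temperature series) so the
  whole chain is testable against known truth without any instrument data.

## Worked example

The numbered drivers under `analysis/` run the complete study on a
synthetic panel (2 discharge frequencies × 5 activation times × 6
seedlings, plus temperature recordings):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_calibrate.R
Rscript analysis/03_signatures.R
Rscript analysis/04_thermal.R
Rscript analysis/05_stats_dose_response.R
```

Stage 2 and 5 print, for the default seed:

```
Calibrated 60 wells.
Resting [Ca2+]cyt: 9.99e-08 M (median); evoked peaks up to 6.27e-07 M.
```

```
Group means with letters (different letters differ at p < 0.05):
           group n     mean       se letters
  DBD_12kHz_3min 6 0.000266 3.99e-06       a
  DBD_12kHz_5min 6 0.000305 7.29e-06       b
  DBD_20kHz_3min 6 0.000310 3.83e-06       b
  DBD_20kHz_5min 6 0.000336 3.14e-06       c
 DBD_12kHz_10min 6 0.000359 5.24e-06       d
 ...
Spearman rho (energy vs mean integrated signal): 0.988
Saturating fit: half-saturation at 114 kJ/kg, R^2 = 0.991
```

Read: the median resting level and peak heights are in the physiological
range the calibration targets; the integrated 30-min signal (`mean`, M·s)
rises with activation time and frequency, and treatments sharing a letter
are statistically indistinguishable; pooled across both frequencies the
response follows one saturating curve in transferred energy per unit mass
(true half-saturation in the generator: 100 kJ/kg), flattening at high
dose.

The same chain is available as a single call:

```r
library(pawsig)
res <- run_pipeline(run_config(seed = 1), out_dir = "results/run")
res$dose_response
```

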