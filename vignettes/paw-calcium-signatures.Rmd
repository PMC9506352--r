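---
title: "Quantifying PAW-induced calcium signatures from aequorin luminescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PAW-induced calcium signatures from aequorin luminescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawsig)
```

## The measurement and the models

Plants expressing cytosolic aequorin report changes in cytosolic free
calcium, [Ca²⁺]~cyt~, as light: each aequorin molecule emits photons when it
binds Ca²⁺ and is irreversibly consumed in doing so. A plate reader visits
each well every 5 s and integrates photons over a 500 ms window; the
treatment (plasma-activated water, PAW) is injected at 100 s, and the run
ends with a discharge solution (1 M CaCl₂ / 30% ethanol) that saturates the
reporter and burns off the remaining pool. The discharge is what makes the
recording calibratable: the total light still to come at any moment measures
the pool still alive.

`pawsig` implements this chain end to end, together with a forward
simulator, so every stage can be validated against known ground truth:

1. **Forward model** (`make_ca_trajectory`, `make_luminescence`) — invents
   nothing downstream: a ground-truth [Ca²⁺]~cyt~ trajectory is pushed
   through the same rate-constant physics the calibration inverts.
2. **Calibration** (`calibrate_trace`) — photon counts to molar Ca²⁺.
3. **Signatures** (`signature_metrics`, `two_dose_analysis`) — peak, onset
   delay, rise slope, integrated dynamics.
4. **Thermal dose** (`fit_thermal`, `transferred_energy`) — the energy per
   unit mass transferred to the water, the dose axis on which treatments
   from different plasma sources are compared.
5. **Statistics** (`pairwise_tests`, `letter_display`,
   `build_dose_response`).

## The calcium trajectory model

The package uses a minimal phenomenological form able to reproduce both
regimes observed in PAW-treated seedlings — transients that dissipate within
about 10 minutes (short water-activation times) and sustained elevations
(long activation times):

$$
\mathrm{Ca}(t) = b \;+\; A\,\frac{e^{-\Delta t/\tau_d} - e^{-\Delta
t/\tau_r}}{\max(\cdot)} \;+\; S\left(1 - e^{-\Delta t/\tau_s}\right),
\qquad \Delta t = t - t_{stim},
$$

with baseline $b$, transient amplitude $A$ (the double exponential is
rescaled so its maximum is exactly $A$), and sustained amplitude $S$. Before
the stimulus the trace equals $b$ exactly. The transient's peak time has the
closed form $\Delta t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)$
(the $\tau_r = \tau_d$ limit is handled analytically), and the integral over
any window is available in closed form (`kinetics_auc`); both are used as
oracles in the test suite.

Defaults are order-of-magnitude choices typical of plant resting and evoked
[Ca²⁺]~cyt~, not published values: resting baseline $10^{-7}$ M, evoked
amplitudes up to a few $10^{-7}$ M. They are parameters, not constants.

## Photon counting and pool depletion

The aequorin consumption rate constant $k$ (s⁻¹) is tied to Ca²⁺ through
the empirical calibration line

$$
\mathrm{pCa} = 0.332588\,(-\log_{10} k) + 5.5593 ,
$$

the standard curve for cytosolic aequorin reconstituted with native
coelenterazine; both constants are exposed in `calibration_params()` so an
alternative curve drops in. The forward simulator inverts this line: the
trajectory sets $k(t)$, and each sample draws

$$
\mathrm{counts}_i \sim \mathrm{Poisson}\!\left(L_i\,(1 -
e^{-k_i w})\right), \qquad L_{i+1} = L_i e^{-k_i w},
$$

with $w$ = 0.5 s the integration window and $L_i$ the remaining pool in
units of *recordable* counts. Two conventions are worth stating plainly:

* **The pool depletes over the integration window, per sample.** The pool is
  the total light the detector would ever record, so the recorded counts and
  the pool decrement are the same quantity; summed counts then conserve the
  initial pool exactly in expectation (the test suite checks conservation to
  1% under Poisson noise). Consumption during the unobserved 4.5 s between
  windows is deliberately not modelled — modelling it would break the
  tail-sum calibration identity by the duty-cycle factor.
* **Expected counts equal $k L w$ to first order** ($k w \ll 1$ everywhere
  except the discharge, where the exact exponential form keeps the decrement
  bounded by the pool).

The discharge is modelled as a step of Ca²⁺ to $10^{-4}$ M; the implied $k$
(~5 × 10⁴ s⁻¹) consumes the pool within a single sample, which is all that
matters — the exact level is irrelevant once $k w \gg 1$.

## Calibration

`calibrate_trace` composes three steps, each exported for inspection:

1. `remaining_pool`: tail sum of background-subtracted counts from each
   sample to the end of the run. This is the consumption correction — no
   further correction is applied.
2. `rate_constant`: $k_i = (\mathrm{counts}_i / w) / \mathrm{remaining}_i$,
   for samples before the discharge. Zero-count samples are floored at
   `k_floor` ($10^{-6}$ s⁻¹ by default) rather than dropped, keeping traces
   on a uniform grid for integration. $k$ is a ratio of counts to counts,
   hence invariant to detector gain.
3. `calibrate_ca`: the pCa line above.

Round-trip accuracy (simulate → calibrate → compare) is better than 5%
relative RMS on samples with at least 50 counts at a pool of 10⁷ counts;
the error is Poisson-dominated ($\approx 0.33/\sqrt{N}$ for $N$ counts,
the 0.33 being the calibration slope) and grows as the pool depletes.

## Signature metrics

All metrics are computed per epoch (one epoch per dose injection):

* **Baseline**: mean over the 60 s before the injection (all pre-stimulus
  samples if fewer than 3 fall there). Each epoch in a multi-dose run uses
  its *local* baseline.
* **Peak**: maximum and its time; ties break to the earliest time.
* **Onset delay**: first sample after the injection exceeding baseline + 3
  pre-stimulus SD, with 2-sample persistence to reject single-sample noise;
  the 3-SD threshold is a choice (exposed as `threshold_sd`) — the assay
  literature shows onset delays but does not define them. Zero pre-stimulus
  variance falls back to a 5%-above-baseline threshold, flagged.
  Non-responders are censored at the window length and flagged, so group
  statistics remain computable.
* **Rise slope**: ordinary least squares from onset to peak. The alternative
  (maximum finite difference) was rejected as noise-sensitive.
* **Integrated dynamics**: trapezoidal integral of the calibrated values
  over 30 min (single dose) or 45 min (two-dose protocol), with *no*
  baseline subtraction — the assay's integrated quantity is the values
  themselves.

## The thermal dose

During activation the water obeys the zero-dimensional heat balance

$$
\frac{d}{dt}\big(m(t)\,c_s\,T\big) = P_{in} - R_{cond}(T - T_{env}),
$$

whose constant-mass solution is $T(t) = T_0 e^{-Bt} + (A/B)(1-e^{-Bt})$ with
$A = (P_{in} + R_{cond}T_{env})/(m_0 c_s)$ and $B = R_{cond}/(m_0 c_s)$.
`fit_thermal` estimates the two physical parameters in two decoupled
stages — cooling first ($P_{in}=0$ isolates $B$, by Levenberg–Marquardt with
a log-linear start), then heating with $B$ fixed (linear in $T_0$ and
$A/B$) — because a joint fit on short series leaves $A$ and $B$ poorly
separated. $T_{env}$ is treated as a measured input for the same
identifiability reason. A non-positive $B$ estimate (loss-free data) falls
back to the linear-heating fit with $R_{cond}=0$, flagged.

The dose is then $E/m = \hat P_{in}\,t_{act}/m_0$ (J/kg). With 0.1 K
measurement noise, 180 s heating + 300 s decay at 5 s sampling, both
parameters are recovered within 10% in ≥95% of replicates; the closed form
and an independent `deSolve` integration of the ODE agree to 10⁻⁶ relative
tolerance, and the ODE path also covers the torch case where ejected water
makes $m(t)$ decrease (linear model, user-supplied rate; the closed form
refuses that case). Temperatures are handled in °C throughout — only
differences enter the model.

## Statistics

Group comparisons use the classical pooled-variance Student t-test, matching
the assay's reported statistics; Welch and Holm correction exist behind
flags but default off — a faithful-reproduction choice, not a
recommendation. The compact letter display uses the insert-and-absorb
algorithm and guarantees the display contract exactly: two groups share a
letter **iff** their pairwise test is non-significant at α. The test suite
verifies this against a brute-force clique-cover oracle on all random
significance graphs it generates.

## What the synthetic experiment emulates — and what it does not

`make_experiment` maps each treatment's transferred energy $E$ to response
size by the saturating rule $\mathrm{AUC}_{true} \propto E/(E+E_{half})$
(applied to the above-baseline integral; strictly increasing, concave),
scales both amplitude components by a per-well lognormal factor (10% CV,
biological replicate variability), and simulates Poisson photon counts per
well. Chosen once and documented: effective DBD power 5 W (of a 10–100 W
nominal source, most power never reaches the water), $E_{half} = 10^5$ J/kg
(mid-panel for 3–30 min activations of 20 mL), resting baseline $10^{-7}$ M.

Passing tests on this generator demonstrate that the *pipeline* recovers
what the generator encodes — calibration inverts the forward model,
signature metrics match closed forms, the fitted dose–response is
saturating. They do not demonstrate anything about real seedlings: real
traces have correlated (non-Poisson) well-to-well structure, drifting
baselines, pipetting artefacts at injection, and a dose→kinetics map that no
one knows. The generator is a test instrument, not a claim about biology.

With 6 replicates and 10% biological CV, the *strict* per-segment concavity
of the measured dose–response means holds at most seeds but not all —
adjacent energies whose true means differ by less than sampling error can
invert a secant. The ground-truth ledger is exactly concave by
construction, and the suite asserts strict concavity there; on measured
means it asserts it under a fixed seed.

## Numerical and degenerate-input conventions

* Pool depletion uses the exact per-step exponential decrement, not an Euler
  step, so the discharge step cannot overshoot the pool.
* Zero-count samples: floored at `k_floor`, never dropped.
* A trace with no counts after background subtraction refuses to calibrate.
* Premature pool exhaustion before the discharge is a flagged condition
  (`"pool_exhausted"`), not an error — the trace is still calibratable, with
  inflated late-trace error.
* Integration grids must be strictly increasing; duplicate (well, time) rows
  in plate files are rejected naming the well.
* All simulators take explicit integer seeds and restore the caller's RNG
  state; identical seeds reproduce runs byte-identically.

## Problem sizes

The shipped analysis (`analysis/01…05`) simulates 60 wells (2 frequencies ×
5 activation times × 6 seedlings) at 1 Hz ground-truth resolution and 5 s
sampling over 2000 s runs, plus ten temperature series — a few seconds end
to end. The test suite's heaviest blocks are the 200-replicate thermal
recovery and the 2000-simulation t-test calibration, each around a second.
These sizes were picked to exercise every code path at the experiment's
actual scale (the assay processes 6 seedlings at a time).

## Known limitations

* The calibration constants are the field's empirical line; if a different
  aequorin isoform or coelenterazine analogue is used, supply your own
  `calibration_params()`.
* The heat model is zero-dimensional; plume inhomogeneity, evaporative
  cooling and stirring are all folded into $P_{in}$ and $R_{cond}$.
  "Effective power" is the fitted $P_{in}$, with no attempt to separate
  evaporative losses.
* Onset delay is threshold-based; very slow sustained rises in noisy wells
  are detected late or censored by design.
* The two-dose analysis truncates each epoch at the next injection; a
  response still decaying when the second dose arrives contaminates the
  second epoch's baseline, which the local-baseline rule mitigates but
  cannot remove.
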