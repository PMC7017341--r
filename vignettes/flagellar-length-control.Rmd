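---
title: "Balance-point length control and IFT quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balance-point length control and IFT quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagbalance)
```

This vignette explains the models implemented in **flagbalance**, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## The balance-point model

Flagellar microtubules disassemble at their tips at a rate *D* (µm/min)
that does not depend on length. Assembly requires intraflagellar transport
(IFT): trains of IFT particles carry tubulin to the tip, and the rate at
which IFT material is injected into the flagellum falls off approximately
as 1/*L*. Assuming assembly is proportional to injection and to the free
precursor pool (total pool *P*, in µm length-equivalents, minus the 2*L*
already built into the cell's two flagella), length obeys

$$\frac{dL}{dt} = \frac{A\,(P - 2L)}{L} - D ,$$

with the lumped injection coefficient *A* (µm/min) absorbing the injection
vs length proportionality, the length increment per delivered cargo, and
the (length-independent) cargo-binding equilibrium. Setting the rate to
zero gives the unique steady state

$$L^\* = \frac{P}{2 + D/A},$$

which is stable: the assembly hyperbola decreases in *L*, so the rate is
positive below *L\** and negative between *L\** and *P*/2. For a mutation
that multiplies *A* by a factor *f* while leaving *P* and *D* alone, the
lengths satisfy

$$\frac{L_M}{L_{wt}} = \frac{2 + D/A_{wt}}{2 + (D/A_{wt})/f},$$

always **less** than *f* for *f* > 1 and approaching *f* only when
*D*/*A* ≫ 2. This bound is the scientific crux: measured injection folds
of 1.5–1.8 in the *lf* mutants translate, at *D*/*A* = 8, into predicted
length folds of only 1.4–1.5, below the observed 1.7–2.0.

**Parameters.** Only the ratio *D*/*A* is empirically constrained (6–8
from flagellar-number experiments; the analyses use the high end, 8,
exposed everywhere as `d_over_a`). Absolute values of *A*, *P*, *D* are
not; `default_model_params()` (A = 0.25 µm/min, P = 120 µm, D = 2 µm/min)
is chosen so D/A = 8, the steady state sits at a realistic 12 µm and
regeneration completes on the hour scale. These defaults are illustrative,
not fitted, and are documented as such.

**Numerics.** `simulate_regeneration()` integrates the scalar ODE with
deSolve's adaptive-step lsoda; the user-facing `dt` only sets the
reporting grid. The equation is singular at *L* = 0, so the right-hand
side clamps internal trial evaluations at a floor of 10⁻³ µm, and any
reported trajectory that reaches the floor (or *P*/2, pool exhaustion) is
rejected with a diagnostic rather than silently continued. Severed-
flagellum regeneration is simulated with the full pool; no reduced
effective pool is applied, since the pool depletion term (*P* − 2*L*)
already covers the regrowth regime of interest. The coupled dynamics of
two unequal flagella are deliberately out of scope — the (*P* − 2*L*)
term encodes the biflagellate pool only for equal lengths.

## Kymograph quantification

A kymograph is a space × time image (rows = position along the flagellum,
row 1 = base; columns = frames) in which an anterograde train is a
straight streak of common slope. The quantifier:

1. **Background, first pass.** Subtracts each column's lower decile. A
   median would be biased upward: at typical train densities the traces
   and their Gaussian skirts cover a third or more of a column, so the
   median sits inside the signal distribution and subtracting it erases
   real trace mass (up to 30% of magnitude in dense images).
2. **Angle search.** Shear-and-sum projection with linear interpolation
   (one direction of a Radon transform; nearest-neighbour shearing
   aliases at fine angles) over a uniform grid of angles measured from
   the space axis — 15° to 90° in 0.25° steps by default, anterograde
   orientations only, retrograde signal being treated as structured
   background — followed by continuous golden-section/parabolic
   refinement between the neighbouring grid points. The selected angle
   maximises max − min of the projected profile, evaluated on fully
   sampled bins only (bins near the intercept extremes sum fewer columns,
   and any residual uniform background would otherwise dominate the
   contrast through that ramp). Speed converts exactly from the angle:
   `speed = (pixel_size/frame_interval)/tan(angle)`, 90° = stationary.
   A single dominant angle is assumed; sub-populations of speeds are not
   modelled.
3. **Peak detection.** Local maxima of the profile that rise at least
   `min_prominence_frac` (default 0.2) of (max − baseline) above the
   baseline (the profile's lower quartile) and are separated by at least
   `min_separation` bins (default 3 px). Both thresholds are exposed
   because no canonical values exist.
4. **Magnitudes, second pass.** With trace positions known, the traces
   are masked in the raw image (support ± 2 px along each line), each
   column's background is re-estimated as the **mean of its unmasked
   pixels** — an unbiased estimator once the signal is excised — and the
   image is re-projected; each train's magnitude is the integral of the
   re-projected profile over the peak's valley-to-valley support, minus a
   per-bin residual level estimated from off-peak bins scaled by each
   bin's exact column count. On synthetic ground truth this two-pass
   scheme recovers mean magnitudes to within ~3% at SNR 5, where a
   single-pass median scheme erred by 10–30%.
5. **Frequency.** (Number of peaks − 1) divided by the time between the
   first and last train departure (computed from peak intercepts), not
   the movie duration; the alternative denominator is available via
   `frequency_denominator = "duration"`. With fewer than two moving
   trains the frequency is undefined and flagged, never guessed.
6. **Injection rate** is frequency × mean magnitude, by definition.

Magnitudes stay in arbitrary fluorescence units; no conversion to
particle counts is attempted. Images consistent with pure noise (profile
contrast below 6 × the robust noise level scaled by the summed column
count) are rejected with an error rather than quantified.

## Injection scaling and strain tables

Per-flagellum injection rates are fitted against length by ordinary least
squares on log10–log10 axes (unweighted; each flagellum is one
observation). Two wild-type reference lines are always carried side by
side: the free-slope best fit, and the fit constrained to slope −1 (the
1/*L* law), whose intercept is the mean of log10(rate) + log10(L). A
strain's mean log10 deviation from a reference line is the log of its
injection fold change; folds are 10^deviation and are fed **unrounded**
into the mutant length prediction — the only convention that reproduces
every printed one-decimal table cell. Presentation rounding is half away
from zero (`round_half_away()`), matching the printed values; base R's
round-half-to-even would not. Log base 10 is used throughout, the only
base consistent with the printed deviation→fold pairs (10^0.24 → 1.7,
10^0.25 → 1.8, …). No hypothesis tests between strains are performed, and
cell-level correlation between the two flagella of one cell is not
modelled.

## The cargo-occupancy null model

Occupancy experiments score the fraction of IFT **trains** carrying a
cargo (tubulin) signal, but binding happens at the level of IFT
**particles**, and trains contain fewer particles in longer flagella
(mean train size N = 16 − 9.96 log10 L, valid below ~40.5 µm where the
line stays positive; requests outside that range are an error, not an
extrapolation). Under the null hypothesis of length-independent binding,
a train of *N* particles with per-particle binding probability
*P*bound is empty with probability

$$P_{empty} = (1 - P_{bound})^N, \qquad
  \log_{10} P_{empty} = N \log_{10}(1 - P_{bound}),$$

so log-emptiness is exactly linear in *N* with zero intercept, and train
occupancy rises toward 1 as trains grow even at constant per-particle
binding — an apparent length dependence with no regulation behind it.

`estimate_p_bound()` regresses log10(1 − fraction occupied) on *N*
(predicted from each observation's length) through the origin, recovering
*P*bound = 1 − 10^slope; a free-intercept variant is available purely as
a diagnostic for departures from the null form. Observations with
occupancy exactly 1 have infinite log-emptiness and are excluded with a
warning and a count — at high *P*bound and large *N* this exclusion is
the dominant error source, since the marginally included points (one
empty train out of fifty) are upward-biased. Real-valued *N* is used when
predicting from length (the fit line gives non-integer means), while the
synthetic sampler rounds to the nearest integer and clamps at a minimum
of 1 particle; the rounding convention is not empirically constrained.
Digitising published occupancy scatter from figures is out of scope; the
comparison is reproduced on synthetic data instead.

## Synthetic data: what it emulates, and what it does not

All three generators are deterministic given a seed and return their
ground truth alongside the data.

* `make_kymograph()` renders straight anterograde traces with Gaussian
  cross-section (SD 1.5 px) at a common speed over a uniform background
  (default 5 a.u., standing in for camera offset and out-of-focus
  fluorescence and keeping the noise floor clear of the zero-clipping
  boundary) plus additive Gaussian noise. Defaults mirror the imaging
  regime the quantifier targets: 0.1 µm/px, 0.05 s/frame, 10 µm
  flagellum, 2 µm/s trains, ~0.7–1 departures/s, amplitude 10 a.u. with
  20% train-to-train variation. Departures are Poisson by default; the
  evenly spaced mode exists for exact-frequency validation, and recovery
  tests use it because under Poisson departures two trains can leave
  within one trace width and physically merge into a single streak that
  no projection method can split. Not emulated: optical point-spread and
  TIRF penetration physics, retrograde traffic, pausing, photobleaching.
  Passing recovery tests therefore demonstrates correctness of the
  geometry, calibration and integration logic, not robustness to every
  imaging artefact of real data.
* `make_scaling_dataset()` draws per-strain lengths from truncated
  normals and rates from `fold × c/L × 10^ε` with ε ~ N(0, σ). Defaults
  reproduce the measured strain layout: wild type 9.9 ± 2.9 µm on the
  trend (c = 50 a.u.·µm/s, giving ~5 a.u./s at 10 µm), lf1 17.9 ± 2.5 µm
  at fold 1.7, lf2-1 16.7 ± 4.3 µm at fold 1.5, lf4 19.9 ± 8.4 µm at
  fold 1.7, with log10 scatter SDs 0.16/0.14/0.11/0.17 taken from the
  per-strain deviation SDs about the 1/L line. The narrow wild-type
  length range (~0.25 log10 units) leaves the free slope poorly
  constrained at n = 30 — which is why fold recovery is assessed against
  the slope −1 reference, and why the free-slope fold can wander by
  several tenths at this sample size.
* `make_occupancy_dataset()` scores binomial cargo draws per train at 20
  log-spaced lengths from 2 to 28 µm (spanning train sizes ~13 down to
  ~2) with 50 trains per length.

## Problem sizes and validation summary

The test suite and drivers validate, at sizes chosen to exercise the
estimators well into their asymptotic behaviour while keeping each run
comfortably interactive: steady-state structure and the ratio bound over
randomised parameter grids; integrator convergence under reporting-grid
refinement; (A, D) recovery from a noiseless trajectory to within 1%;
kymograph recovery over 20 seeded images at SNR 5 (speed within 5%,
frequency within 10%, magnitude within 10% of truth); binding-probability
recovery over 100 seeded occupancy datasets at *P*bound ∈ {0.2, 0.5, 0.8}
(pooled median absolute error < 0.03 — errors are smallest at 0.2, where
few observations saturate); and injection-fold recovery at n = 30 per
strain over 10 seeds (seed-averaged folds within 0.2 of the planted
values). No empirical claim is made beyond what those tests and the
`analysis/` drivers themselves compute.

## Known limitations

* Only the ratio D/A is identifiable from the analyses implemented here;
  absolute rate parameters are illustrative.
* The kymograph model assumes one dominant anterograde speed; mixed
  speed populations, pausing and retrograde quantification are out of
  scope, as is converting fluorescence to particle counts.
* Train magnitude decomposition becomes ambiguous when departures
  cluster within a trace width; merged trains are reported as one.
* The occupancy estimator inherits the exclusion bias of saturated
  observations at high binding probability; reporting the saturated
  count makes the effect visible but does not remove it.
* The injection analysis treats flagella as independent observations;
  any within-cell correlation would shrink effective sample sizes.
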