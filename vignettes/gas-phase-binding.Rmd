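---
title: "Models and methods: gas-phase immune-complex dissociation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: gas-phase immune-complex dissociation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoCID)
```

## The experiment being modelled

An intact monoclonal antibody (~147 kDa) is incubated with a synthetic
epitope peptide (here: 15-mers covering residues 184–198 of human cardiac
troponin I, wild type plus single-amino-acid-polymorphism variants) and
electrosprayed natively. The quadrupole blocks low-mass ions, so the
detector sees the multiply charged antibody and antibody–peptide complex
ions (charge states around 23+ to 27+, m/z 5000–7000). The collision-cell
voltage difference (ΔCV) is stepped through 2, 4, 6, 8, 12, 16, 20, 30, 40,
50, 60, 70 and 80 V; at each step the complex dissociates further and the
released peptide appears at 2+/3+ in the low-mass range. The fraction of
signal still held by the intact complexes — the *educt* — declines
sigmoidally with ΔCV, and the shape of that decline carries the gas-phase
binding strength.

## Spectrum processing

Per step, scans are averaged pointwise (mismatched axes are linearly
interpolated onto a common grid; total ion current is preserved to within
1%). Spectra are then smoothed with an iterated Savitzky–Golay filter.
The filter order is not dictated by the experiment's vendor software, so we
use order 2 — the standard choice that preserves peak area and apex position
to second order — and read the nominal "window of 10" as 10 data points,
widened to 11 because a symmetric kernel needs odd length. Twenty smoothing
cycles are applied by default, matching common practice for these broad
native-MS envelopes.

Species heights are apex readings: the maximum smoothed intensity within a
tolerance window around the expected m/z of each (species, charge) pair,
where expected positions follow from the antibody mass (configured or
deconvoluted) plus 0, 1 or 2 peptide masses. Default tolerances are
5 Th for the antibody-containing species (broad peaks near m/z 6000) and
0.5 Th for the peptide. Windows with no recorded points are flagged missing;
windows whose maximum does not exceed the background return the background.
When two distinct apices (separated by a valley below 75% of the smaller)
fall inside one window, the taller is used and a collision warning is
raised; the check is gated on a noise floor so that pure-noise windows do
not alarm.

The background is the median intensity over configured signal-free windows
(default m/z 4400–4700, below the lightest antibody charge state); its
median absolute deviation doubles as the noise-floor estimate.

Per species, the per-charge apex heights are fitted with a Gaussian over
charge, `h·exp(−(z − c)²/(2w²))`. The fit needs at least five points; when
fewer charge states are measured, flanking charge states are appended *at
the background intensity*, alternating below and above the measured range
(starting below), and flagged as imputed. The Gaussian amplitude is the
species height and the center `c` is the mean charge. If the
Levenberg–Marquardt fit fails on a degenerate point set, a coarse grid
search takes over. All-background point sets are non-detects: the apex is
the background and the center undefined.

The released peptide shows only two charge states (2+, 3+), too few for a
meaningful five-point Gaussian; its height is therefore read directly at
its strongest signal (2+). The normalized educt fraction is

```
educt % = 100 · (h_complex1 + h_complex2) / (h_antibody + h_complex1 + h_complex2 + h_peptide)
```

Antibody fragment ions are excluded from the denominator by default: they
appear only at high ΔCV, where counting them alongside the released peptide
would double-count dissociation products. A configuration switch restores
them for sensitivity analyses.

Zero-charge masses are deconvoluted from consecutive charge-state peaks:
adjacent peaks `m1 > m2` imply the charge `z = round((m2 − p)/(m1 − m2))`
of the lower-charge peak, and per-peak masses `z·m − z·p` are averaged.
Peaks whose per-peak masses spread more than 50 ppm indicate interleaved
series from different species and are rejected.

## Boltzmann course analysis

The replicate-mean educt course is fitted with
`y(x) = A2 + (A1 − A2)/(1 + exp((x − x0)/dx))`. Initial values: `A1` and
`A2` from the course extremes, `x0` from the first linearly interpolated
midpoint crossing, `dx` as a tenth of the voltage range. The solver is
bounded — plateaus within [0, 100]%, midpoint within the probed voltage
window, `dx` positive — because unbounded four-parameter sigmoid fits of
13-point courses occasionally collapse into degenerate optima under noise.
The parameterization has a sign ambiguity (`(A1, A2, dx)` and
`(A2, A1, −dx)` describe the same curve); fits are normalized to the
dissociation orientation `dx > 0`. Fitting is unweighted on the replicate
means by default, with optional 1/SD² weighting. `R²` is
`1 − SS_res/SS_tot` on the fitted means, and the central tangent slope is
`−(A1 − A2)/(4·dx)` exactly.

Courses whose dynamic range is below 10 percentage points show no
dissociation transition and are refused rather than fitted: a weakly,
unorthodoxly bound peptide drifts from ~15% to ~6% over the whole voltage
range (range ~9.5 points) without a sigmoid step, and forcing a sigmoid
through such a drift would fabricate a midpoint. Masked points are
recorded, never silent: the quality gate's third criterion fails whenever
an exclusion was applied.

## Quality gate

A measurement series enters downstream analysis when at least three of four
criteria hold:

1. *Species differentiation*: at the lowest ΔCV, free antibody and both
   complexes are distinguishable in at least five charge states. We read
   the verbal "minimum difference of at least 50%" as a valley criterion —
   between adjacent species signals the intensity must dip to at most 50%
   of the smaller apex (boundary inclusive). The reading is exposed as an
   option because the vendor-software definition is not recoverable.
2. *Sodium adducts*: at ΔCV = 80 V, the sodium-adduct 2+ signal must not
   exceed 35% of the protonated peptide 2+ signal. For series without any
   released-peptide signal (non-binders) the criterion is undecidable and
   recorded as a pass with a warning — such series were analyzed in the
   original study design and must not be auto-excluded.
3. *No outliers excluded* from the Boltzmann fit.
4. *Fit accuracy*: R² ≥ 0.99 (inclusive).

The gate is monotone by construction: improving any criterion can only
preserve or gain a pass.

## Apparent kinetics and thermodynamics

The published chain of extrapolations from course parameters to apparent
values lives in protocols whose defining equations are not restated in the
experiment description; this package implements a documented
reconstruction from the four named relations and the stated anchors
(20,000 atoms for the antibody, source temperature 313 K, ambient reference
298 K):

1. Along the fitted course, the normalized survival
   `s(x) = (y(x) − A2)/(A1 − A2)` at each voltage step (kept between 5% and
   95%, i.e. off the plateaus) is converted to a first-order rate constant
   `k = −ln(s)/τ` with the collision-cell residence time `τ` (default 1 ms,
   configurable; the true transit time is instrument-dependent).
2. Each (charge state, voltage) pair deposits a center-of-mass collision
   energy `E = z·e·ΔCV·N_A·m_gas/(m_gas + M)·n_collisions` (argon; the
   collision multiplier defaults to 1 and is exposed because
   multi-collision heating is instrument-dependent), raising the effective
   internal temperature to `T_eff = T_source + E/((3N − 6)R)` with
   N = 20,000 atoms.
3. Eyring–Polanyi converts rates to activation equilibrium constants
   `K = k·h/(k_B·T_eff)`.
4. An Arrhenius regression of `ln k` on `1/T_eff` extrapolates the rate to
   298 K (`kD`); a van't Hoff regression of `ln K` on `1/T_eff` gives the
   apparent dissociation enthalpy ΔH (slope) and, evaluated at 298 K, the
   apparent dissociation constant `KD`. Then `ΔG = −R·298·ln KD/1000` and
   `TΔS = ΔH − ΔG`, so the Gibbs–Helmholtz identity and
   `KD = exp(−ΔG/(R·T))` hold *exactly by construction* — these identities,
   not the absolute magnitudes, are the tested surface. Absolute `kD`/`KD`
   magnitudes depend on the unpublished extrapolation constants and the
   deposited raw dataset and are explicitly not claimed.

With fewer than two distinct effective temperatures the chain falls back to
a single-point mode (midpoint rate `ln 2/τ`) and leaves the van't Hoff
quantities undetermined.

Binder groups: IV ("non-binder") when no complex signal exists at the
lowest voltage (initial educt ≤ 0.5%, a numeric stand-in for "zero" under
noise); III ("weak/unorthodox") when complexes form but no valid transition
exists; among orthodox binders, I ("very strong") when ΔH > −2 kJ/mol and
II ("strong") otherwise. Rankings order groups first, then ΔH within
groups.

## Independent-model ITC fit

Injection heats are modelled with the single-site (Wiseman) isotherm. With
`n` sites per cell macromolecule at concentration `M`, total ligand `L`,
the bound-site fraction Θ solves
`Θ² − Θ(1 + L/(nM) + 1/(n·K_A·M)) + L/(nM) = 0` (smaller root). Each
injection displaces cell volume (perfusion model: both cell species dilute
by `1 − v/V0`, ligand is replenished), and the injection heat carries the
standard displaced-volume correction
`q_i = Q_i − Q_{i−1} + (v_i/V0)(Q_i + Q_{i−1})/2` with
`Q = n·Θ·M·V0·ΔH`. The first injection is excluded from the objective by
default (syringe-tip diffusion), and `n` is fitted freely by default (an
antibody offers two Fab sites). Flat heat traces — standard deviation and
mean below 0.05 µJ — are refused as "not binding" rather than fitted.
Derived values are exact identities: `K_D = 1/K_A`,
`ΔG = −RT ln K_A` (referenced to 1 M), `TΔS = ΔH − ΔG`.

## The synthetic-data generator

The generator emulates the study conditions and serves as ground truth for
every closed-loop test. Defaults: antibody 146,756.2 Da, wild-type peptide
1813.907 Da, charge states 23–27 with a Gaussian charge envelope centered
at 25 (width 1.2), thirteen voltage steps 2–80 V, educt decay following the
wild-type course parameters (77.36%, 36.24%, 30.0 V, 15.2 V), 70% of educt
signal in the one-peptide complex (the two-peptide complex is the minor
species; the true split is not reported, 0.7/0.3 is a modelling choice),
and a released-peptide signal growing with the dissociated share.

Intensities are bookkept as *envelope apex heights* — the currency in which
spectra are read — and the four species' apexes sum exactly to the total
intensity at every step, which makes the noise-free closed loop
(simulate → process → course) exact to numerical precision. Peaks are
simple Gaussians in m/z without isotope structure; sodium adducts appear
only on the peptide 2+ signal (+21.981943 Da); optional broadband
antibody-fragment signal (m/z 1200–2300) is off by default. The m/z grid
samples both mass ranges at the same points-per-peak density (peak sd / 5),
as a time-of-flight analyser approximately does — iterated smoothing then
attenuates all species alike and height ratios survive processing. Additive
Gaussian noise (SD = `noise_sd` × total intensity) is drawn under the
recipe seed; negative intensities are clamped at zero.

What the generator does *not* emulate — detector shot noise, isotope fine
structure, charge stripping, in-source dimers, m/z calibration drift —
bounds what passing tests show about real data: they validate the
estimators and the algebra, not vendor-specific peak shapes.

## Numerical choices and problem sizes

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`), 500 iterations
  maximum; envelope fits fall back to a coarse grid search.
* At 2-percentage-point course noise the midpoint estimate of a 13-point
  course has an intrinsic spread of several volts; recovery studies
  therefore report the *median* over many replicates. The acceptance
  script uses 5000 replicates (a few seconds of compute) so that the
  median's own sampling error (~0.1 V) is negligible; the test suite uses
  200–5000 depending on the property. Full-spectrum closed-loop tests use
  single series at fixed seeds, where midpoint recovery within ~2 V
  reflects the additional apex-reading noise of the spectrum stage.
* Confidence-interval calibration is checked at 0.1-point noise, where the
  estimator is in its linear regime (median error < 0.3 V, 95% interval
  coverage within [90%, 99%]).

## Known limitations

* Absolute apparent `kD`/`KD` magnitudes are reconstruction-dependent
  (residence time, collision multiplier) and are reported for relative
  ranking, not as instrument-calibrated values.
* The vendor's smoothing and the 50%-differentiation reading may differ in
  detail from the order-2 Savitzky–Golay filter and the valley criterion
  used here; both are exposed as options.
* No isotope deconvolution, no multi-site or sequential ITC models, no
  vendor raw-file decoding (mzML and a CSV-manifest dialect are the input
  formats).
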