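---
title: "Quantifying dynamic FDG-PET in a mouse tumor model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic FDG-PET in a mouse tumor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynPET)
```

## Scope and model

`dynPET` quantifies dynamic [¹⁸F]FDG PET scans of small animals carrying
orthotopic liver tumors. FDG is transported into cells and trapped after
phosphorylation, so tissue kinetics are described by the irreversible
two-tissue compartment (2TC) model with plasma-to-tissue transport `K1`
(mL·min⁻¹·mL⁻¹), efflux `k2` (min⁻¹), trapping `k3` (min⁻¹) and fractional
blood volume `vb`. Its macro-parameter, the net influx rate
`Ki = K1·k3/(k2+k3)`, is estimated by Patlak graphical analysis: plotting
`C_ROI(T)/Cp(T)` against `∫₀ᵀ Cp dt / Cp(T)` yields a late-time straight
line with slope `Ki` and intercept `Int` (an apparent distribution volume,
nonnegative for irreversible kinetics in the absence of noise).

The analysis assumes:

* decay-corrected activity concentrations in kBq/mL, corrected during
  reconstruction (the reader never re-corrects);
* an irreversible tracer (`k4 = 0`); reversible Patlak and Logan analysis
  are out of scope;
* linearity of the plot from `t* = 10` min onward, which holds when the
  free compartment turns over fast enough (`k2 + k3` of roughly
  0.25 min⁻¹ or more — see "Known limitations");
* a plasma input obtainable from the images: the vena-cava TAC scaled to
  the liver TAC at the final frame, times a plasma-to-blood equilibrium
  ratio `r(t) = r_eq + (r0 − r_eq)·e^(−t/τ_r)`.

Downstream, `MRGlu = Cglu·Ki/LC` converts influx into a glucose metabolic
rate using the scan-average blood glucose `Cglu` (mmol/L, numerically
µmol/mL, so MRGlu is in µmol·min⁻¹·mL⁻¹) and organ lumped constants
(tumor 1, brain 0.625, heart 0.67). Semiquantitative metrics are
body-weight SUV — tissue density taken as 1 g/mL, the standard rodent
convention, with the single MBq→kBq factor of 1000 applied inside the SUV
formula and nowhere else — and `SUVglu = SUV × Cglu`.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `t*` | 10 | min | onset of Patlak linearity for the assessed organs; overridable per fit |
| ratio `r0`, `r_eq`, `τ_r` | 1.0, 1.2, 5 | —, —, min | the exact in-vivo ratio function is not published for this model; a saturating exponential with these constants gives a plausible 20% plasma excess at equilibrium, and the constants are exposed |
| lumped constants | 1 / 0.625 / 0.67 | — | tumor / brain / heart conversion factors used by the study design |
| SUV window | 45–60 | min | static uptake window of the PET/MR protocol (scan started 45 min p.i.) |
| Feng input `A1..λ3` | 851.1, 21.9, 20.8; 4.13, 0.45, 0.012 | kBq/mL(/min); min⁻¹ | peak inside the first 2 min, mouse-like fast distribution phase (t₁/₂ ≈ 1.5 min) so the tail is effectively mono-exponential by `t*`, slow terminal clearance |
| phantom noise scale | 1.0 | (kBq/mL·min)^½ | per-voxel SD = scale·√(value/duration): short frames and hot voxels are noisier, a quadrature stand-in for counting statistics |
| growth σ_animal, σ_meas | 0.4, 0.1 | log-scale | inter-animal volume CVs of tens of percent are typical for orthotopic implantation; measurement error is a much smaller multiplicative term |

The input-function family deserves a note: no measured arterial input is
available for this model, so the simulator uses the Feng tri-exponential
form that is standard in FDG kinetics. Its distribution-phase rate was
chosen *before* freezing the recovery tests so that the input satisfies the
same property the analysis assumes of the real data — a Patlak plot that is
linear after 10 min. A slower, human-like phase (λ₂ ≈ 0.12 min⁻¹) leaves a
visible transient at `t* = 10` and a ~2% systematic slope bias even without
noise; that parameterisation remains available and its curve-shape
properties are tested.

## What the phantom emulates — and what it does not

`buildPhantomSession()` voxelizes disjoint ellipsoids (tumor, brain,
heart, liver, vena cava) on a configurable grid (default 64×64×96 voxels
of 0.4×0.4×0.8 mm) and fills them with frame-averaged 2TC curves under the
23-frame/60-min schedule; the vena cava carries the whole-blood curve and
the liver is rescaled so its last-frame value equals the blood last-frame
value times a configurable factor (default 1.0 — exactly the assumption
the IDIF scaling step makes). Session metadata defaults to the week-1
dynamic-group values (9.0 MBq, 25.9 g, glucose 9.9 mmol/L).

Deliberately *not* modelled: scanner physics (attenuation, scatter,
randoms, reconstruction artifacts), partial-volume effects and spill-over
into the small vena-cava VOI, respiratory motion, dispersion/delay between
blood pools, and intratumoral heterogeneity (each organ is kinetically
uniform). Passing recovery tests therefore demonstrate correctness of the
estimation chain, not robustness to those physical effects; on real data
the IDIF step in particular inherits partial-volume bias, which the scale
covariance property (input ×c ⇒ Ki ÷c) makes explicit.

Organ `vb` defaults to 0 in the phantom presets: a nonzero blood fraction
biases the graphical slope by about `−vb` relative to the compartmental
`Ki` (the blood term contributes almost no late-time slope), and the
recovery suite targets the compartmental value. `vb` is implemented and
can be switched on to study exactly that bias.

## Numerical choices

* **Frame reference time** is the frame mid-time, `(start + dur/2)/60`
  min — the standard estimator for frame-averaged values.
* **Plasma running integral** (Patlak abscissa) is frame-based:
  Σ duration×mean over preceding frames plus half the current frame. This
  is exact when frame means are exact, whereas a trapezoid on the sparse
  late mid-time grid adds ~0.5% systematic bias; integration starts at
  injection (t = 0), never at `t*`.
* **AUC** uses trapezoids with a virtual (0, 0) anchor (activity is zero
  at injection) and extends past the last mid-time with the last frame
  mean, so a 0–60 min AUC covers the full final frame.
* **ODE integration** uses `deSolve::lsoda` on a grid of ≤1 s steps,
  refined to ≤0.25 s over the first two minutes where the bolus curvature
  dominates the frame-average error.
* **Degenerate fits**: a zero-variance Patlak ordinate returns `Ki = 0`,
  `Int = y`, `R² = 0` with a degenerate flag; identical abscissa values
  are a singular-fit error; fewer than three post-`t*` frames is an
  insufficient-data error. A nonpositive growth slope reports an infinite
  doubling time rather than a negative one.
* **Negative TAC values** (possible after reconstruction corrections) are
  clipped to zero before IDIF scaling, with a reported count.
* **Tidy CSV output** writes values at 17 significant digits so
  read-after-write is bit-exact.

## Open design decisions

* The VOI mean is the unweighted mean over member voxels, and tumor volume
  is voxel counting × voxel volume; plane-wise weighting alternatives are
  not implemented.
* Patlak fitting is unweighted OLS on the included frames; no frame
  weighting scheme is assumed.
* The Patlak ordinate is the standard `C_ROI(T)/Cp(T)`. An alternative
  reading that substitutes the tissue AUC for the tissue value exists in
  the literature around this protocol; it is exposed as
  `patlakPoints(..., tissueIntegral = TRUE)` for comparison only, because
  it is not the linearization whose slope is `Ki`.
* Doubling times are fitted per animal by log-linear OLS and summarized
  by the cohort mean.
* Growth noise factors are *mean-one* lognormals (meanlog = −σ²/2), so
  the calibrated preset's cohort mean equals `V0·2^(d/Td)` for any noise
  level and the weekly-mean calibration is noise-invariant. With
  meanlog = 0 the means would inflate by `e^{σ²/2}` (~9% at the default
  σs), entangling calibration with noise settings.
* Two growth presets coexist: `"weekly-means"` (log-linear fit of the
  weekly cohort means 18/44/127/332 mm³ at days 7.7/15/22/29, giving
  `Td ≈ 5.0` d, `R² = 0.998`) and `"reported-doubling"` (`Td = 6.4` d,
  anchored at the week-1 mean). The two disagree — per-animal fits over a
  full study can legitimately differ from a fit of cohort means — and the
  package documents rather than reconciles them. Note the least-squares
  calibration does not interpolate the four means exactly: residuals reach
  ~8% at week 2, which bounds how closely any exponential cohort can
  reproduce them.

## Problem sizes used by the test suite

Recovery properties run at sizes chosen to make the checks sharp yet quick
to reproduce: noise-free Patlak recovery over an FDG-physiological grid
(K1 ∈ {0.05, 0.1, 0.2}, k2 ∈ {0.2, 0.3}, k3 ∈ {0.05, 0.1}, i.e.
Ki 0.007–0.05 with k2+k3 ≥ 0.25 min⁻¹) at 1% tolerance; noisy recovery as
100 seeded end-to-end phantom replicates on a 32×32×48 grid (median
absolute Ki bias < 10%); growth calibration at 10,000 simulated animals;
doubling-time recovery on 20-animal cohorts. Phantom geometry is specified
in grid fractions, so the full 64×64×96 default and the smaller test grid
share identical kinetics and differ only in voxel counts.

## Known limitations

* **Patlak transient bias for slow tissues.** The linearized plot only
  approaches slope `Ki` once `e^{−(k2+k3)t}` has decayed. At `t* = 10` min
  a tissue with `k2+k3 = 0.12` min⁻¹ still shows a ~7% positive slope
  bias with a noise-free input — an intrinsic property of the method, not
  an implementation artifact. For such kinetics `t*` must be raised (it
  is an argument everywhere).
* The vena-cava IDIF is taken at face value: no partial-volume or
  dispersion correction.
* `MRGlu` inherits the uncertainty of the lumped constants; tumor LC = 1
  is a convention, not a measurement.
* The regression screen (`regressMetricOnGlucose`) is simple linear
  regression; it reproduces the *machinery* of the glucose-dependence
  analysis, but published per-animal regression statistics cannot be
  recomputed without the underlying per-animal data, which are not
  deposited. The property-based suites (recovery, covariance, null
  p-value uniformity) stand in for them.
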