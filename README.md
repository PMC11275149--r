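# dynPET

Kinetic quantification of dynamic [¹⁸F]FDG PET/MR in small-animal tumor
models, built for preclinical imaging groups that monitor orthotopic tumors
(here, a cholangiocarcinoma mouse model) weekly with dynamic FDG scans and
contrast-enhanced MR volumetry. The package covers the whole quantification
chain — time–activity curves, an image-derived plasma input function, Patlak
graphical analysis, glucose-normalized uptake metrics, and tumor doubling
times — and ships a two-tissue-compartment phantom simulator so every stage
can be validated end to end without scanner data.

## The model

Tissue FDG kinetics follow the irreversible two-tissue compartment model

    dC1/dt = K1·Cp(t) − (k2 + k3)·C1,    dC2/dt = k3·C1,
    CT(t) = (1 − vb)·(C1 + C2) + vb·Cb(t)

whose net influx rate is `Ki = K1·k3/(k2 + k3)`. For an irreversibly
trapped tracer the Patlak linearization

    C_ROI(T)/Cp(T) = Ki · ∫₀ᵀ Cp dt / Cp(T) + Int

becomes a straight line once the free compartment equilibrates (here after
t\* = 10 min); `Ki` is the slope of an ordinary least-squares fit over the
late frames.

The plasma input `Cp` is image-derived: the vena-cava TAC is scaled to the
liver TAC at the last time frame (whole-blood recovery), then multiplied by
a time-dependent plasma-to-blood equilibrium ratio
`r(t) = r_eq + (r0 − r_eq)·e^(−t/τ_r)`.

Downstream metrics:

* `MRGlu = Cglu·Ki / LC` (µmol·min⁻¹·mL⁻¹), with `Cglu` the mean of the
  pre- and post-scan blood glucose (mmol/L) and organ lumped constants
  LC = 1 (tumor), 0.625 (brain), 0.67 (heart);
* `SUV(t) = C(t) / (1000·A_inj/W)` (body-weight SUV, density 1 g/mL) and
  `SUVglu = SUV × Cglu`;
* tumor doubling time `Td = ln 2 / slope` from a log-linear fit of volume
  on day.

The simulator generates voxelized phantom sessions (Feng tri-exponential
plasma input, per-organ 2TC curves, a vena-cava blood pool, counting-like
frame noise) on the 23-frame/60-min mouse schedule
(8×5 s, 2×10 s, 2×30 s, 3×60 s, 2×150 s, 2×300 s, 4×600 s), plus lognormal
exponential-growth cohorts calibrated to weekly cohort-mean volumes.

## Worked example

```r
library(dynPET)

cfg <- phantomConfig(gridDim = c(32, 32, 48), noiseScale = 0)
ses <- buildPhantomSession(cfg, seed = 1)

tumor <- extractTac(ses@image, ses@mask, "tumor")
inp   <- buildPlasmaInput(extractTac(ses@image, ses@mask, "vena_cava"),
                          extractTac(ses@image, ses@mask, "liver"),
                          cfg$inputParams)
(fit  <- patlakEstimate(tumor, inp, schedule(ses@image)))
#> PatlakResult: Ki = 0.019908 mL/min/mL, Int = 0.3441, R^2 = 1.0000 (t* = 10 min, n = 6)

cglu <- averageBloodGlucose(ses@glucosePre, ses@glucosePost)
metabolicRateGlucose(fit, cglu, "tumor")
#> MetabolicResult (tumor): MRGlu = 0.19709 umol/min/mL (Cglu = 9.9 mmol/L, LC = 1)
```

The fitted slope 0.019908 mL·min⁻¹·mL⁻¹ recovers the phantom's ground
truth `Ki = 0.02` (K1 = 0.1, k2 = 0.2, k3 = 0.05) within 0.5%; the R² of
1.0000 confirms the plot is linear past 10 min; MRGlu is the influx rate
converted to a glucose flux at the session's 9.9 mmol/L blood glucose.

Growth analysis works the same way from tidy volume records:

```r
pm <- growthPreset("weekly-means")      # V0 = 5.95 mm^3, Td = 5.01 d
cohort <- generateGrowthCohort(pm, 20, seed = 1)
mean(cohortDoublingTimes(cohort)$doubling_time)
#> [1] 5.037241
```

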