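test_that("Feng plasma input starts at zero, peaks early and then decays monotonically", {
  # both the package defaults and a slower, human-like parameterisation
  paramSets <- list(
    inputModelParams(),
    inputModelParams(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                     lambda1 = 4.13, lambda2 = 0.12, lambda3 = 0.01))
  for (p in paramSets) {
    expect_equal(fengPlasmaInput(p, 0), 0)
    tt <- seq(0, 60, by = 0.005)
    cp <- fengPlasmaInput(p, tt)
    expect_true(all(cp >= 0))
    peak <- tt[which.max(cp)]
    expect_lt(peak, 2)            # peak within the first two minutes
    after <- cp[tt > peak]
    expect_true(all(diff(after) <= 1e-9))  # monotone decay past the peak
  }
  # linearity in the amplitudes
  p <- inputModelParams()
  p2 <- inputModelParams(A1 = 2 * p@A1, A2 = 2 * p@A2, A3 = 2 * p@A3)
  tt <- seq(0, 60, by = 0.1)
  expect_equal(fengPlasmaInput(p2, tt), 2 * fengPlasmaInput(p, tt))
  # invariant violations are rejected
  expect_error(inputModelParams(lambda1 = 0.1, lambda2 = 0.45), "lambda")
  expect_error(fengPlasmaInput(p, c(-1, 0)), class = "dynPET_parameter_error")
})

test_that("plasma-to-blood ratio behaves as a saturating exponential and inverts exactly", {
  pIdent <- inputModelParams(r0 = 1, rEq = 1, tauR = 5)
  tt <- seq(0, 60, by = 0.5)
  expect_equal(plasmaToBloodRatio(pIdent, tt), rep(1, length(tt)))
  p <- inputModelParams(r0 = 1, rEq = 1.2, tauR = 5)
  expect_equal(plasmaToBloodRatio(p, 60), 1.2, tolerance = 1e-5)
  # blood_from_plasma and plasma_input_from_blood are exact inverses
  plasma <- fengPlasmaInput(p, tt)
  blood <- bloodFromPlasma(plasma, tt, p)
  tac <- makeTac(tt[-1], blood[-1], organ = "whole_blood")
  recovered <- plasmaInputFromBlood(tac, p)
  expect_equal(values(recovered), plasma[-1], tolerance = 1e-13)
  # r0 = rEq = 1 means blood == plasma
  expect_identical(bloodFromPlasma(plasma, tt, pIdent), plasma)
})

test_that("simulated tissue curves match the closed-form 2TC solution", {
  p <- inputModelParams()
  sched <- mouseFrameSchedule()
  plasmaFun <- function(t) fengPlasmaInput(p, t)
  cases <- list(c(0.1, 0.2, 0.05), c(0.05, 0.3, 0.1), c(0.2, 0.3, 0.02))
  for (cs in cases) {
    gt <- kineticGroundTruth(cs[1], cs[2], cs[3])
    sim <- values(simulateTissueTac(gt, plasmaFun, sched))
    ora <- frameAvgOracle(function(t) tissueOracle(t, p, cs[1], cs[2], cs[3]),
                          sched)
    expect_equal(sim, ora, tolerance = 1e-5)
  }
  # K1 = 0: nothing enters the tissue
  null <- values(simulateTissueTac(kineticGroundTruth(0, 0.2, 0.05),
                                   plasmaFun, sched))
  expect_equal(null, rep(0, 23), tolerance = 1e-12)
  # k3 = 0: reversible tracer equilibrates at tissue/plasma ~ K1/k2
  gt0 <- kineticGroundTruth(0.1, 1.0, 0)
  sim0 <- values(simulateTissueTac(gt0, plasmaFun, sched))
  cpLast <- frameAvgOracle(function(t) fengOracle(t, p), sched)[23]
  expect_equal(sim0[23] / cpLast, 0.1 / 1.0, tolerance = 0.03)
  expect_equal(trueKi(gt0), 0)
})

test_that("noise-free phantom VOI curves equal the analytic per-organ curves", {
  ses <- buildPhantomSession(smallPhantomConfig(noiseScale = 0), seed = 7)
  img <- ses@image; mask <- ses@mask
  for (org in names(ses@groundTruth$curves)) {
    tac <- extractTac(img, mask, org)
    expect_equal(values(tac), ses@groundTruth$curves[[org]],
                 tolerance = 1e-12, label = org)
    expect_gte(tac@nVoxels, 1L)
  }
  # vena cava carries the whole-blood curve
  expect_equal(values(extractTac(img, mask, "vena_cava")),
               ses@groundTruth$blood, tolerance = 1e-12)
  # liver last frame equals blood last frame times the configured factor
  lv <- values(extractTac(img, mask, "liver"))
  expect_equal(lv[23], ses@groundTruth$blood[23] * 1.0, tolerance = 1e-12)
})

test_that("phantom sessions are seed-reproducible and reject overlapping organs", {
  a <- buildPhantomSession(smallPhantomConfig(noiseScale = 1), seed = 11)
  b <- buildPhantomSession(smallPhantomConfig(noiseScale = 1), seed = 11)
  expect_identical(values(a@image), values(b@image))
  expect_identical(a@mask@labels, b@mask@labels)
  c <- buildPhantomSession(smallPhantomConfig(noiseScale = 1), seed = 12)
  expect_false(identical(values(a@image), values(c@image)))
  expect_true(all(values(a@image) >= 0))

  bad <- smallPhantomConfig()
  bad$geometry$tumor$center <- bad$geometry$liver$center
  expect_error(buildPhantomSession(bad, seed = 1),
               class = "dynPET_config_error")
})

test_that("growth cohorts follow exponential growth with mean-one noise", {
  # one doubling, noise-free
  p <- growthModelParams(V0 = 10, doublingTime = 7, sigmaAnimal = 0,
                         sigmaMeas = 0, measurementDays = c(0, 7))
  co <- generateGrowthCohort(p, 1, seed = 1)
  expect_equal(co$volume, c(10, 20))
  # law of large numbers against the closed-form mean (mean-one factors)
  pm <- growthPreset("weekly-means")
  big <- generateGrowthCohort(pm, 10000, seed = 42)
  d29 <- big$volume[big$day == 29]
  modelMean <- pm@V0 * 2^(29 / pm@doublingTime)
  se <- stats::sd(d29) / sqrt(length(d29))
  expect_lt(abs(mean(d29) - modelMean), 4 * se)
  expect_true(all(big$volume > 0))
  # determinism
  expect_identical(generateGrowthCohort(pm, 50, seed = 3),
                   generateGrowthCohort(pm, 50, seed = 3))
  # presets: calibrated vs reported doubling time disagree by design
  expect_equal(growthPreset("reported-doubling")@doublingTime, 6.4)
  expect_lt(pm@doublingTime, 6.4)
  expect_gt(pm@doublingTime, 4)
})
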