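test_that("Patlak variables reduce to known identities", {
  sched <- mouseFrameSchedule()
  mt <- midTimes(sched)
  # constant input: x(T) = T exactly (frame-based running integral)
  const <- makeInput(mt, rep(7, 23))
  tis <- makeTac(mt, rep(7, 23))
  pts <- patlakPoints(tis, const, sched)
  expect_equal(pts@x, mt, tolerance = 1e-12)
  # tissue identical to input: y = 1
  expect_equal(pts@y, rep(1, 23))
  expect_identical(which(pts@include), which(mt >= 10))
  # too few late frames
  expect_error(patlakPoints(tis, const, sched, tStar = 50),
               class = "dynPET_insufficient_data")
  # zero plasma at an included frame
  bad <- makeInput(mt, c(rep(7, 22), 0))
  expect_error(patlakPoints(tis, bad, sched),
               class = "dynPET_degenerate_input")
})

test_that("the OLS fit recovers exact lines and flags degenerate ordinates", {
  sched <- mouseFrameSchedule()
  mt <- midTimes(sched)
  cp <- fengPlasmaInput(inputModelParams(), mt)
  inp <- makeInput(mt, cp)
  pts0 <- patlakPoints(makeTac(mt, cp), inp, sched)
  # build a tissue curve that lies exactly on y = 0.02 x + 0.3
  ct <- cp * (0.02 * pts0@x + 0.3)
  fit <- patlakFit(patlakPoints(makeTac(mt, ct), inp, sched))
  expect_equal(fit@Ki, 0.02, tolerance = 1e-12)
  expect_equal(fit@intercept, 0.3, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_false(fit@degenerate)
  # constant ordinate: Ki = 0, Int = y, R^2 reported as 0
  flat <- patlakFit(patlakPoints(makeTac(mt, 0.5 * cp), inp, sched))
  expect_equal(flat@Ki, 0)
  expect_equal(flat@intercept, 0.5)
  expect_equal(flat@rSquared, 0)
  expect_true(flat@degenerate)
})

test_that("Patlak on simulated irreversible kinetics is collinear with slope Ki", {
  p <- inputModelParams()
  sched <- mouseFrameSchedule()
  plasmaFun <- function(t) fengPlasmaInput(p, t)
  tis <- simulateTissueTac(kineticGroundTruth(0.1, 0.2, 0.05), plasmaFun, sched)
  inp <- makeInput(midTimes(sched), frameAveragedCurve(plasmaFun, sched))
  fit <- patlakEstimate(tis, inp, sched)
  expect_equal(fit@Ki, 0.02, tolerance = 0.01)
  expect_gt(fit@rSquared, 0.999)
  expect_gte(fit@intercept, 0)  # distribution-volume intercept
})

test_that("multiplying the input by c divides the fitted Ki by exactly c", {
  p <- inputModelParams()
  sched <- mouseFrameSchedule()
  plasmaFun <- function(t) fengPlasmaInput(p, t)
  tis <- simulateTissueTac(kineticGroundTruth(0.1, 0.2, 0.05), plasmaFun, sched)
  cp <- frameAveragedCurve(plasmaFun, sched)
  base <- patlakEstimate(tis, makeInput(midTimes(sched), cp), sched)
  for (c0 in c(0.5, 2, 10)) {
    scaled <- patlakEstimate(tis, makeInput(midTimes(sched), c0 * cp), sched)
    expect_equal(scaled@Ki, base@Ki / c0, tolerance = 1e-10)
  }
})

test_that("scan-average glucose handles both, one, or no measurements", {
  expect_equal(averageBloodGlucose(8, 12), 10)
  expect_equal(averageBloodGlucose(9.9, 9.9), 9.9)
  expect_warning(g <- averageBloodGlucose(7.5, NA), "pre-scan")
  expect_equal(g, 7.5)
  expect_error(averageBloodGlucose(NA_real_, NA_real_),
               class = "dynPET_missing_data")
  expect_error(averageBloodGlucose(-1, 5), class = "dynPET_parameter_error")
})

test_that("MRGlu algebra: lumped constants, linearity and exact inversion", {
  m <- metabolicRateGlucose(0.02, 9.9, "tumor")
  expect_equal(m@mrglu, 0.198)
  expect_equal(m@lumpedConstant, 1)
  # brain LC = 0.625 means MRGlu = 1.6 x (Cglu x Ki)
  mb <- metabolicRateGlucose(0.02, 9.9, "brain")
  expect_equal(mb@mrglu, 1.6 * 9.9 * 0.02)
  expect_equal(metabolicRateGlucose(0.02, 9.9, "heart")@lumpedConstant, 0.67)
  # zero influx gives zero metabolic rate
  expect_equal(metabolicRateGlucose(0, 12, "tumor")@mrglu, 0)
  # unknown organ without an explicit LC
  expect_error(metabolicRateGlucose(0.02, 9.9, "kidney"),
               class = "dynPET_lookup_error")
  expect_equal(metabolicRateGlucose(0.02, 9.9, lc = 2)@mrglu, 0.099)
  # property: MRGlu * LC / Cglu returns Ki exactly; linear in Cglu and Ki
  set.seed(21)
  for (i in 1:25) {
    ki <- stats::runif(1, 0.001, 0.05)
    cg <- stats::runif(1, 4, 15)
    org <- sample(names(lumpedConstants()), 1)
    mm <- metabolicRateGlucose(ki, cg, org)
    expect_equal(mm@mrglu * mm@lumpedConstant / cg, ki, tolerance = 1e-12)
    expect_equal(metabolicRateGlucose(2 * ki, cg, org)@mrglu, 2 * mm@mrglu)
    expect_equal(metabolicRateGlucose(ki, 2 * cg, org)@mrglu, 2 * mm@mrglu)
  }
})

test_that("SUVglu is the plain product of SUV and glucose", {
  expect_equal(suvGlu(1, 9.9), 9.9)
  expect_equal(suvGlu(0, 12.3), 0)
  expect_equal(suvGlu(1.5, 10), 15)
  expect_equal(suvGlu(c(1, 2), 10), c(10, 20))
  expect_error(suvGlu(-1, 10), class = "dynPET_parameter_error")
})
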