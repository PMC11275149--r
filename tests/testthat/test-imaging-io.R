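test_that("frame schedules enforce contiguity, positivity and zero start", {
  s <- mouseFrameSchedule()
  expect_s4_class(s, "FrameSchedule")
  expect_equal(nFrames(s), 23L)
  expect_identical(totalDuration(s), 3600)
  expect_equal(frameStarts(s)[-1],
               head(frameStarts(s) + frameDurations(s), -1))
  expect_equal(midTimes(s)[1], (0 + 2.5) / 60)
  expect_true(all(diff(midTimes(s)) > 0))

  expect_error(frameSchedule(c(0, 10), c(10, -5)), "positive")
  expect_error(frameSchedule(c(0, 20), c(10, 10)), "contiguous")
  expect_error(frameSchedule(c(5, 15), c(10, 10)), "injection")
})

test_that("dynamic image read/write is the identity and validates the sidecar", {
  sched <- frameSchedule(durations = c(5, 5, 10, 40))
  arr <- array(stats::runif(6 * 5 * 4 * 4, 0, 100), dim = c(6, 5, 4, 4))
  img <- dynamicImage(arr, c(0.4, 0.4, 0.8), sched)
  vp <- tempfile(fileext = ".nii"); sp <- tempfile(fileext = ".json")
  writeDynamicImage(img, vp, sp)
  back <- readDynamicImage(vp, sp)
  expect_identical(dim(values(back)), dim(arr))
  expect_equal(values(back), arr, tolerance = 0)
  expect_equal(frameStarts(schedule(back)), frameStarts(sched))
  expect_equal(frameDurations(schedule(back)), frameDurations(sched))
  expect_equal(voxelSpacing(back), c(0.4, 0.4, 0.8))

  # sidecar with one frame too few -> format error
  jsonlite::write_json(list(frame_starts_s = c(0, 5, 10),
                            frame_durations_s = c(5, 5, 10)),
                       sp, auto_unbox = FALSE)
  expect_error(readDynamicImage(vp, sp), class = "dynPET_format_error")
  # non-contiguous sidecar -> validation error
  jsonlite::write_json(list(frame_starts_s = c(0, 9, 10, 20),
                            frame_durations_s = c(5, 1, 10, 40)),
                       sp, auto_unbox = FALSE)
  expect_error(readDynamicImage(vp, sp), class = "dynPET_validation_error")
})

test_that("mask read/write round-trips labels and names, and errors are typed", {
  lab <- array(0L, c(6, 5, 4))
  lab[1:2, 1:2, 1] <- 1L; lab[4, 4, 2] <- 2L; lab[6, 1, 4] <- 3L
  mask <- voiMask(lab, c(tumor = 1, liver = 2, heart = 3))
  mp <- tempfile(fileext = ".nii"); np <- tempfile(fileext = ".json")
  writeMaskSet(mask, mp, np)
  back <- readMaskSet(mp, np)
  expect_identical(back@labels, lab)
  expect_identical(sort(names(back@labelNames)), sort(names(mask@labelNames)))

  img <- dynamicImage(array(1, c(6, 5, 4, 2)), c(1, 1, 1),
                      frameSchedule(durations = c(30, 30)))
  expect_silent(checkSameGrid(back, img))
  img2 <- dynamicImage(array(1, c(3, 3, 3, 2)), c(1, 1, 1),
                       frameSchedule(durations = c(30, 30)))
  expect_error(checkSameGrid(back, img2), class = "dynPET_grid_mismatch")

  # organ named but absent from the grid -> empty-VOI error on access
  mask2 <- voiMask(lab, c(tumor = 1, brain = 9))
  expect_error(extractTac(img, mask2, "brain"), class = "dynPET_empty_voi")
  expect_error(extractTac(img, mask2, "kidney"), class = "dynPET_lookup_error")
})

test_that("session manifests validate rows, sort by week and tolerate a missing post glucose", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,week,injected_activity_mbq,body_weight_g,glucose_pre_mmol_l,glucose_post_mmol_l",
    "m1,2,9.6,26.9,10.0,10.0",
    "m1,1,9.0,25.9,9.9,9.9",
    "m1,4,11.0,26.9,10.7,10.7",
    "m1,3,10.3,27.0,10.0,10.0"), p)
  ss <- loadSessionManifest(p)
  expect_length(ss, 4)
  expect_equal(vapply(ss, function(s) s@week, 1L), 1:4)
  expect_equal(ss[[1]]@injectedActivity, 9.0)
  expect_equal(ss[[1]]@bodyWeight, 25.9)
  expect_equal(ss[[1]]@glucosePre, 9.9)

  writeLines(c(
    "subject_id,week,injected_activity_mbq,body_weight_g,glucose_pre_mmol_l",
    "m2,1,8.0,27.0,7.5"), p)
  expect_warning(ss2 <- loadSessionManifest(p), "post-scan glucose")
  expect_true(is.na(ss2[[1]]@glucosePost))
  expect_equal(suppressWarnings(
    averageBloodGlucose(ss2[[1]]@glucosePre, ss2[[1]]@glucosePost)), 7.5)

  writeLines(c(
    "subject_id,week,injected_activity_mbq,body_weight_g,glucose_pre_mmol_l,glucose_post_mmol_l",
    "m3,1,9.0,0,9.9,9.9"), p)
  expect_error(loadSessionManifest(p), class = "dynPET_validation_error")
})

test_that("tidy result tables have stable order and round-trip numerics exactly", {
  rec <- data.frame(
    subject = c("m2", "m1", "m1", "m2"), week = c(2L, 1L, 1L, 2L),
    organ = "tumor", metric = c("Ki", "Ki", "suv_mean", "suv_mean"),
    value = c(0.021, 1 / 3, exp(1), pi), units = "a.u.")
  p <- tempfile(fileext = ".csv")
  out <- writeTidyResults(rec, p)
  expect_equal(nrow(out), 4)
  expect_equal(out$subject, c("m1", "m1", "m2", "m2"))
  back <- readTidyResults(p)
  expect_identical(back$value, out$value)  # bit-exact via %.17g

  empty <- writeTidyResults(rec[0, ], p)
  expect_equal(nrow(empty), 0)
  expect_equal(names(readTidyResults(p)),
               c("subject", "week", "organ", "metric", "value", "units"))
})

test_that("acquisition-geometry arithmetic reproduces protocol voxel sizes", {
  expect_equal(round(voxelSizeFromFov(76, 217), 2), 0.35)
  expect_equal(round(voxelSizeFromFov(40, 53), 3), 0.755)
  expect_equal(voxelSizeFromFov(c(30, 28), c(86, 80)), c(30 / 86, 0.35))
})
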