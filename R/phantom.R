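#' @include AllClasses.R synthetic-tissue.R imaging-io.R
NULL

#' Default organ kinetics for the phantom
#'
#' FDG two-tissue parameters (K1, k2, k3 in mL·min^-1·mL^-1 / min^-1)
#' typical of the modelled organs, all with turnover k2 + k3 >= 0.25 min^-1
#' so that the graphical analysis is in its linear regime after 10 min --
#' the regime the pipeline assumes. The tumor preset has Ki = 0.02. The
#' liver is reversible (k3 = 0); its late frames are rescaled against the
#' blood curve when the phantom is assembled (see
#' \code{\link{buildPhantomSession}}).
#'
#' @return named list of \code{\link{KineticGroundTruth}}.
#' @export
defaultOrganKinetics <- function() {
  list(tumor = kineticGroundTruth(0.10, 0.20, 0.05),
       brain = kineticGroundTruth(0.15, 0.25, 0.06),
       heart = kineticGroundTruth(0.20, 0.30, 0.10),
       liver = kineticGroundTruth(0.30, 0.50, 0.00))
}

# Organ ellipsoids as fractions of the grid so any grid size works.
.defaultGeometry <- function() {
  list(brain     = list(center = c(0.50, 0.500, 0.15), radii = c(0.120, 0.120, 0.060)),
       heart     = list(center = c(0.50, 0.375, 0.42), radii = c(0.090, 0.090, 0.050)),
       liver     = list(center = c(0.375, 0.560, 0.65), radii = c(0.160, 0.160, 0.090)),
       tumor     = list(center = c(0.72, 0.625, 0.65), radii = c(0.090, 0.090, 0.050)),
       vena_cava = list(center = c(0.69, 0.375, 0.54), radii = c(0.040, 0.040, 0.150)))
}

#' Phantom configuration
#'
#' Study conditions for one simulated scan session. Defaults emulate the
#' dynamic-PET protocol: the 23-frame/60-min schedule, PET voxels of
#' 0.4 x 0.4 x 0.8 mm, week-1 session metadata (9.0 MBq, 25.9 g, glucose
#' 9.9 mmol/L) and frame-mean noise with variance proportional to
#' value / frame duration (a quadrature approximation to counting noise).
#'
#' @param gridDim integer triple, voxel grid size.
#' @param spacing voxel spacing, mm.
#' @param sched a \code{\link{FrameSchedule}}.
#' @param kinetics named list of \code{\link{KineticGroundTruth}} per organ.
#' @param inputParams an \code{\link{InputModelParams}}.
#' @param noiseScale noise magnitude; SD per voxel-frame =
#'   \code{noiseScale * sqrt(value / duration_min)} kBq/mL. 0 disables noise.
#' @param liverBloodFactor liver last-frame value as a multiple of the
#'   whole-blood last-frame value (1 matches the vena-cava-to-liver scaling
#'   assumption exactly).
#' @param injectedActivity MBq; \code{bodyWeight} g; \code{glucosePre},
#'   \code{glucosePost} mmol/L.
#' @param bodyWeight,glucosePre,glucosePost session metadata.
#' @param subjectId,week session identity.
#' @return a plain list of settings for \code{\link{buildPhantomSession}}.
#' @export
phantomConfig <- function(gridDim = c(64, 64, 96), spacing = c(0.4, 0.4, 0.8),
                          sched = mouseFrameSchedule(),
                          kinetics = defaultOrganKinetics(),
                          inputParams = inputModelParams(),
                          noiseScale = 1.0, liverBloodFactor = 1.0,
                          injectedActivity = 9.0, bodyWeight = 25.9,
                          glucosePre = 9.9, glucosePost = 9.9,
                          subjectId = "phantom-01", week = 1L) {
  list(gridDim = as.integer(gridDim), spacing = spacing, sched = sched,
       kinetics = kinetics, inputParams = inputParams,
       noiseScale = noiseScale, liverBloodFactor = liverBloodFactor,
       injectedActivity = injectedActivity, bodyWeight = bodyWeight,
       glucosePre = glucosePre, glucosePost = glucosePost,
       subjectId = subjectId, week = week,
       geometry = .defaultGeometry())
}

.ellipsoidIndices <- function(gridDim, centerFrac, radiiFrac) {
  cx <- centerFrac * gridDim
  rx <- pmax(radiiFrac * gridDim, 0.8)  # keep >= 1 voxel on coarse grids
  ix <- (slice.index(array(0L, gridDim), 1) - cx[1]) / rx[1]
  iy <- (slice.index(array(0L, gridDim), 2) - cx[2]) / rx[2]
  iz <- (slice.index(array(0L, gridDim), 3) - cx[3]) / rx[3]
  which(ix^2 + iy^2 + iz^2 <= 1)
}

#' Add frame-mean counting noise to a curve or voxel block
#'
#' Gaussian noise with variance proportional to value over frame duration
#' (short frames and hot voxels are noisier), zero-clipped. Uses the current
#' RNG state.
#'
#' @param values numeric vector or matrix (voxels x frames) of kBq/mL.
#' @param durationsMin frame durations in minutes (recycled across rows).
#' @param scale noise magnitude (see \code{\link{phantomConfig}}).
#' @return noisy values, same shape, clipped at zero.
#' @export
addFrameNoise <- function(values, durationsMin, scale) {
  if (scale == 0) return(values)
  v <- as.matrix(values)
  sd <- scale * sqrt(pmax(v, 0) / rep(durationsMin, each = nrow(v)))
  noisy <- pmax(v + stats::rnorm(length(v)) * sd, 0)
  if (is.matrix(values)) noisy else as.vector(noisy)
}

#' Build a voxelized phantom scan session
#'
#' Assembles a complete synthetic session: disjoint ellipsoidal organs
#' filled with their simulated two-tissue TACs, a vena-cava region filled
#' with the whole-blood curve, a liver whose last-frame value equals the
#' blood last-frame value times \code{liverBloodFactor}, optional counting
#' noise, and the session metadata. The simulation ground truth (kinetic
#' parameters, true Ki, noise-free organ curves, input model) is stored in
#' the session for recovery testing.
#'
#' @param config a \code{\link{phantomConfig}} list.
#' @param seed integer RNG seed; the same seed reproduces the session
#'   exactly.
#' @return a \code{\link{ScanSession}} with image, mask and groundTruth.
#' @export
buildPhantomSession <- function(config = phantomConfig(), seed = 1L) {
  set.seed(seed)
  sched <- config$sched
  p <- config$inputParams
  plasmaFun <- function(t) fengPlasmaInput(p, t)
  bloodFun <- function(t) plasmaFun(t) / plasmaToBloodRatio(p, t)
  bloodFrames <- frameAveragedCurve(bloodFun, sched)
  nf <- nFrames(sched)

  organs <- names(config$geometry)
  curves <- list()
  for (org in organs) {
    if (org == "vena_cava") {
      curves[[org]] <- bloodFrames
    } else {
      kin <- config$kinetics[[org]]
      if (is.null(kin))
        .err(sprintf("no kinetics configured for organ '%s'", org),
             "dynPET_config_error")
      cv <- values(simulateTissueTac(kin, plasmaFun, sched, bloodFun, org))
      if (org == "liver") {
        target <- config$liverBloodFactor * bloodFrames[nf]
        cv <- cv * target / cv[nf]
      }
      curves[[org]] <- cv
    }
  }

  gridDim <- config$gridDim
  nspat <- prod(gridDim)
  labels <- array(0L, gridDim)
  occupied <- logical(nspat)
  voiIdx <- list()
  for (i in seq_along(organs)) {
    g <- config$geometry[[organs[i]]]
    idx <- .ellipsoidIndices(gridDim, g$center, g$radii)
    if (any(occupied[idx]))
      .err(sprintf("organ '%s' overlaps another region; adjust geometry",
                   organs[i]), "dynPET_config_error")
    occupied[idx] <- TRUE
    labels[idx] <- i
    voiIdx[[organs[i]]] <- idx
  }

  vals <- array(0, c(gridDim, nf))
  durMin <- frameDurations(sched) / 60
  for (org in organs) {
    idx <- voiIdx[[org]]
    block <- matrix(rep(curves[[org]], each = length(idx)),
                    nrow = length(idx))
    if (config$noiseScale > 0)
      block <- addFrameNoise(block, durMin, config$noiseScale)
    for (f in seq_len(nf))
      vals[idx + (f - 1L) * nspat] <- block[, f]
  }

  image <- dynamicImage(vals, config$spacing, sched)
  mask <- voiMask(labels, stats::setNames(seq_along(organs), organs))
  truth <- list(kinetics = config$kinetics,
                trueKi = lapply(config$kinetics, trueKi),
                curves = curves, blood = bloodFrames,
                inputParams = p, liverBloodFactor = config$liverBloodFactor,
                noiseScale = config$noiseScale, seed = seed)
  scanSession(config$subjectId, config$week, config$injectedActivity,
              config$bodyWeight, config$glucosePre, config$glucosePost,
              image = image, mask = mask, groundTruth = truth)
}
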