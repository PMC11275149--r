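#' @include AllGenerics.R
NULL

.nearly <- function(a, b, tol = 1e-6) abs(a - b) <= tol * pmax(1, abs(b))

#' FrameSchedule: the acquisition time binning of a dynamic scan
#'
#' Frames are contiguous, non-overlapping bins starting at injection
#' (first start = 0); starts and durations are stored in seconds, mid-times
#' are reported in minutes.
#'
#' @slot starts numeric, frame start times in seconds from injection.
#' @slot durations numeric, frame durations in seconds (strictly positive).
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"),
  validity = function(object) {
    s <- object@starts; d <- object@durations
    if (length(s) != length(d)) return("starts and durations differ in length")
    if (length(s) == 0L) return("schedule is empty")
    if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite schedule entries")
    if (any(d <= 0)) return("frame durations must be strictly positive")
    if (abs(s[1L]) > 1e-9) return("first frame must start at injection (t = 0)")
    if (length(s) > 1L) {
      gap <- s[-1L] - (s[-length(s)] + d[-length(d)])
      if (any(abs(gap) > 1e-6))
        return("frames must be contiguous: start[i+1] = start[i] + duration[i]")
    }
    TRUE
  })

#' DynamicImage: a 4-D dynamic PET volume
#'
#' Activity concentration in kBq/mL (decay-corrected to injection time;
#' correction is assumed already applied during reconstruction) on a regular
#' voxel grid, fourth dimension = time frame.
#'
#' @slot values 4-D numeric array, kBq/mL.
#' @slot spacing numeric triple, voxel spacing in mm.
#' @slot schedule a \code{FrameSchedule} whose length matches dim 4.
#' @slot units character, activity-concentration units (kBq/mL).
#' @export
setClass("DynamicImage",
  representation(values = "array", spacing = "numeric",
                 schedule = "FrameSchedule", units = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be a 4-D array (x, y, z, frame)")
    if (d[4L] != length(object@schedule@starts))
      return("number of time points does not match the frame schedule")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("voxel spacing must be three positive numbers (mm)")
    if (any(!is.finite(object@values))) return("image values must be finite")
    TRUE
  })

#' VoiMask: integer label volume naming organs on the image grid
#'
#' @slot labels 3-D integer array on the same spatial grid as its image.
#' @slot labelNames named integer vector, organ name -> label value.
#' @export
setClass("VoiMask",
  representation(labels = "array", labelNames = "integer"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
    if (is.null(names(object@labelNames)) || any(names(object@labelNames) == ""))
      return("labelNames must be a named integer vector (organ -> label)")
    if (anyDuplicated(object@labelNames)) return("duplicate label values")
    if (anyDuplicated(names(object@labelNames))) return("duplicate organ names")
    TRUE
  })

#' ScanSession: one animal-week imaging session
#'
#' Per-scan metadata (injected activity, body weight, pre/post blood
#' glucose) together with, optionally, the dynamic image, VOI mask and --
#' for phantoms -- the simulation ground truth.
#'
#' @slot subjectId character scan subject identifier.
#' @slot week integer imaging week (1--4).
#' @slot injectedActivity numeric, MBq.
#' @slot bodyWeight numeric, g.
#' @slot glucosePre,glucosePost numeric, mmol/L (post may be NA).
#' @slot route character, "iv" or "ip".
#' @slot image a \code{DynamicImage} or NULL.
#' @slot mask a \code{VoiMask} or NULL.
#' @slot groundTruth list of simulation truth (empty for real scans).
#' @export
setClass("ScanSession",
  representation(subjectId = "character", week = "integer",
                 injectedActivity = "numeric", bodyWeight = "numeric",
                 glucosePre = "numeric", glucosePost = "numeric",
                 route = "character", image = "ANY", mask = "ANY",
                 groundTruth = "list"),
  prototype(image = NULL, mask = NULL, groundTruth = list(), route = "iv"),
  validity = function(object) {
    if (!object@week %in% 1:4) return("week must be in 1..4")
    if (!is.finite(object@injectedActivity) || object@injectedActivity <= 0)
      return("injected activity (MBq) must be positive")
    if (!is.finite(object@bodyWeight) || object@bodyWeight <= 0)
      return("body weight (g) must be positive")
    if (!is.finite(object@glucosePre) || object@glucosePre <= 0)
      return("pre-scan glucose (mmol/L) must be positive")
    if (!is.na(object@glucosePost) && object@glucosePost <= 0)
      return("post-scan glucose (mmol/L) must be positive when present")
    if (!object@route %in% c("iv", "ip")) return("route must be 'iv' or 'ip'")
    TRUE
  })

#' TimeActivityCurve: per-frame VOI mean activity
#'
#' @slot midTimes numeric, frame mid-times in minutes, strictly increasing.
#' @slot values numeric, per-frame unweighted VOI means (kBq/mL, or SUV
#'   after conversion).
#' @slot units character, "kBq/mL" or "SUV".
#' @slot organ character VOI name.
#' @slot nVoxels integer number of member voxels.
#' @export
setClass("TimeActivityCurve",
  representation(midTimes = "numeric", values = "numeric", units = "character",
                 organ = "character", nVoxels = "integer"),
  validity = function(object) {
    if (length(object@midTimes) != length(object@values))
      return("times and values differ in length")
    if (any(diff(object@midTimes) <= 0)) return("mid-times must be strictly increasing")
    if (object@nVoxels < 1L) return("a TAC needs at least one voxel")
    if (!object@units %in% c("kBq/mL", "SUV")) return("units must be kBq/mL or SUV")
    TRUE
  })

#' InputFunction: image-derived plasma input curve
#'
#' Plasma activity concentration C_p(t) on the TAC time grid, with the
#' provenance of its construction (vena-cava-to-liver scale factor and
#' plasma-to-blood ratio parameters).
#'
#' @slot midTimes numeric, minutes.
#' @slot plasmaValues numeric, kBq/mL.
#' @slot scaleFactor numeric, liver/vena-cava last-frame ratio applied.
#' @slot ratioParams list, plasma-to-blood ratio model parameters.
#' @export
setClass("InputFunction",
  representation(midTimes = "numeric", plasmaValues = "numeric",
                 scaleFactor = "numeric", ratioParams = "list"),
  validity = function(object) {
    if (length(object@midTimes) != length(object@plasmaValues))
      return("times and values differ in length")
    if (any(!is.finite(object@plasmaValues))) return("plasma values must be finite")
    if (!is.finite(object@scaleFactor) || object@scaleFactor <= 0)
      return("scale factor must be positive")
    TRUE
  })

#' KineticGroundTruth: irreversible two-tissue-compartment parameters
#'
#' @slot K1 numeric, mL·min^-1·mL^-1 (plasma-to-tissue transport).
#' @slot k2 numeric, min^-1 (efflux).
#' @slot k3 numeric, min^-1 (phosphorylation/trapping; 0 = reversible).
#' @slot vb numeric in [0, 1), fractional blood volume.
#' @export
setClass("KineticGroundTruth",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric", vb = "numeric"),
  validity = function(object) {
    if (object@K1 < 0) return("K1 must be nonnegative")
    if (object@k2 <= 0) return("k2 must be positive")
    if (object@k3 < 0) return("k3 must be nonnegative")
    if (object@vb < 0 || object@vb >= 1) return("vb must lie in [0, 1)")
    TRUE
  })

#' InputModelParams: Feng plasma model + plasma-to-blood ratio
#'
#' Tri-exponential (Feng-type) arterial plasma model
#' \eqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#' + A_3 e^{-\lambda_3 t}} and the saturating plasma-to-blood equilibrium
#' ratio \eqn{r(t) = r_{eq} + (r_0 - r_{eq}) e^{-t/\tau_r}}.
#'
#' @slot A1 numeric, kBq·mL^-1·min^-1; \code{A2,A3} kBq/mL.
#' @slot A2,A3 numeric amplitudes, kBq/mL.
#' @slot lambda1,lambda2,lambda3 numeric decay rates, min^-1
#'   (lambda1 > lambda2 > lambda3 > 0).
#' @slot r0,rEq numeric, unitless ratio at t = 0 and at equilibrium.
#' @slot tauR numeric, ratio time constant in minutes.
#' @export
setClass("InputModelParams",
  representation(A1 = "numeric", A2 = "numeric", A3 = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
                 r0 = "numeric", rEq = "numeric", tauR = "numeric"),
  validity = function(object) {
    if (!(object@lambda1 > object@lambda2 && object@lambda2 > object@lambda3 &&
          object@lambda3 > 0))
      return("need lambda1 > lambda2 > lambda3 > 0")
    if (object@r0 <= 0 || object@rEq <= 0 || object@tauR <= 0)
      return("ratio parameters must be positive")
    TRUE
  })

#' GrowthModelParams: exponential tumor-growth simulator settings
#'
#' Volumes grow as \eqn{V(d) = V_0 \cdot 2^{d/T_d}} with mean-one lognormal
#' animal and measurement factors.
#'
#' @slot V0 numeric, mean volume at day 0 (mm^3).
#' @slot doublingTime numeric, days.
#' @slot sigmaAnimal,sigmaMeas numeric log-scale SDs (>= 0).
#' @slot measurementDays numeric, days post-implantation.
#' @export
setClass("GrowthModelParams",
  representation(V0 = "numeric", doublingTime = "numeric",
                 sigmaAnimal = "numeric", sigmaMeas = "numeric",
                 measurementDays = "numeric"),
  validity = function(object) {
    if (object@V0 <= 0) return("V0 must be positive")
    if (object@doublingTime <= 0) return("doubling time must be positive")
    if (object@sigmaAnimal < 0 || object@sigmaMeas < 0)
      return("sigmas must be nonnegative")
    if (length(object@measurementDays) < 1L || any(object@measurementDays < 0))
      return("measurement days must be nonnegative")
    TRUE
  })

#' PatlakPoints: the linearized graphical-analysis variables
#'
#' Abscissa \eqn{x(T) = \int_0^T C_p dt / C_p(T)} (minutes) and ordinate
#' \eqn{y(T) = C_{ROI}(T)/C_p(T)} (unitless), with per-frame inclusion flags
#' (mid-time >= t*).
#'
#' @slot x,y numeric per-frame Patlak variables.
#' @slot include logical, frames entering the fit.
#' @slot tStar numeric, linearity onset in minutes.
#' @export
setClass("PatlakPoints",
  representation(x = "numeric", y = "numeric", include = "logical",
                 tStar = "numeric"),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@include) != n)
      return("x, y and include must have equal length")
    if (sum(object@include) < 3L) return("need >= 3 included points for a fit")
    TRUE
  })

#' PatlakResult: fitted net influx rate
#'
#' @slot Ki numeric, mL·min^-1·mL^-1 (slope).
#' @slot intercept numeric, unitless (Int).
#' @slot rSquared numeric in [0, 1].
#' @slot tStar numeric, minutes.
#' @slot nPoints integer, points in the fit.
#' @slot degenerate logical, TRUE when the ordinate had zero variance.
#' @export
setClass("PatlakResult",
  representation(Ki = "numeric", intercept = "numeric", rSquared = "numeric",
                 tStar = "numeric", nPoints = "integer", degenerate = "logical"),
  validity = function(object) {
    if (object@nPoints < 3L) return("fit needs >= 3 points")
    if (object@rSquared < 0 || object@rSquared > 1) return("R^2 must lie in [0, 1]")
    TRUE
  })

#' MetabolicResult: metabolic rate of glucose
#'
#' @slot mrglu numeric, umol·min^-1·mL^-1.
#' @slot Ki numeric, the net influx rate used.
#' @slot cgluMean numeric, mmol/L.
#' @slot lumpedConstant numeric, unitless (> 0).
#' @slot organ character.
#' @export
setClass("MetabolicResult",
  representation(mrglu = "numeric", Ki = "numeric", cgluMean = "numeric",
                 lumpedConstant = "numeric", organ = "character"),
  validity = function(object) {
    if (object@lumpedConstant <= 0) return("lumped constant must be positive")
    if (is.finite(object@mrglu) && is.finite(object@Ki) &&
        sign(object@mrglu) != sign(object@Ki) && object@Ki != 0)
      return("MRGlu must carry the sign of Ki")
    TRUE
  })

#' GrowthFit: log-linear doubling-time estimate
#'
#' @slot doublingTime numeric, days (Inf when the fitted slope is <= 0).
#' @slot growthRate numeric, day^-1 (slope of ln V on day).
#' @slot v0 numeric, fitted day-0 volume in mm^3.
#' @slot rSquared numeric in [0, 1].
#' @slot nPoints integer.
#' @export
setClass("GrowthFit",
  representation(doublingTime = "numeric", growthRate = "numeric",
                 v0 = "numeric", rSquared = "numeric", nPoints = "integer"),
  validity = function(object) {
    if (object@nPoints < 2L) return("fit needs >= 2 points")
    if (object@rSquared < 0 || object@rSquared > 1) return("R^2 must lie in [0, 1]")
    if (object@growthRate > 0 &&
        !.nearly(object@doublingTime, log(2) / object@growthRate, 1e-8))
      return("doublingTime must equal ln(2)/growthRate for positive growth")
    TRUE
  })

#' CorrelationResult: simple linear regression of a metric on glucose
#'
#' @slot slope,intercept numeric regression coefficients.
#' @slot rSquared numeric in [0, 1].
#' @slot pValue numeric in (0, 1], two-sided test of slope = 0.
#' @slot n integer sample size.
#' @export
setClass("CorrelationResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", pValue = "numeric", n = "integer"),
  validity = function(object) {
    if (object@rSquared < 0 || object@rSquared > 1) return("R^2 must lie in [0, 1]")
    if (object@pValue <= 0 || object@pValue > 1) return("p-value must lie in (0, 1]")
    TRUE
  })

# ---- show methods ----------------------------------------------------------

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %g s total (%.1f min)\n",
              length(object@starts), sum(object@durations),
              sum(object@durations) / 60))
})

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("DynamicImage: %d x %d x %d voxels x %d frames, spacing %s mm, %s\n",
              d[1], d[2], d[3], d[4],
              paste(format(object@spacing), collapse = " x "), object@units))
})

setMethod("show", "VoiMask", function(object) {
  cat(sprintf("VoiMask: %s grid; organs: %s\n",
              paste(dim(object@labels), collapse = " x "),
              paste(names(object@labelNames), collapse = ", ")))
})

setMethod("show", "ScanSession", function(object) {
  cat(sprintf(
    "ScanSession %s week %d: %.1f MBq, %.1f g, glucose %.1f/%s mmol/L (%s)%s\n",
    object@subjectId, object@week, object@injectedActivity, object@bodyWeight,
    object@glucosePre,
    if (is.na(object@glucosePost)) "NA" else sprintf("%.1f", object@glucosePost),
    object@route,
    if (length(object@groundTruth)) " [phantom]" else ""))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s': %d frames, %d voxels, units %s\n",
              object@organ, length(object@values), object@nVoxels, object@units))
})

setMethod("show", "InputFunction", function(object) {
  cat(sprintf("InputFunction: %d frames, peak %.1f kBq/mL, scale factor %.4g\n",
              length(object@plasmaValues), max(object@plasmaValues),
              object@scaleFactor))
})

setMethod("show", "PatlakResult", function(object) {
  cat(sprintf("PatlakResult: Ki = %.5g mL/min/mL, Int = %.4g, R^2 = %.4f (t* = %g min, n = %d%s)\n",
              object@Ki, object@intercept, object@rSquared, object@tStar,
              object@nPoints, if (object@degenerate) ", degenerate" else ""))
})

setMethod("show", "MetabolicResult", function(object) {
  cat(sprintf("MetabolicResult (%s): MRGlu = %.5g umol/min/mL (Cglu = %.3g mmol/L, LC = %g)\n",
              object@organ, object@mrglu, object@cgluMean, object@lumpedConstant))
})

setMethod("show", "GrowthFit", function(object) {
  cat(sprintf("GrowthFit: doubling time %.3g d (rate %.4g /d, V0 %.3g mm^3, R^2 %.4f, n = %d)\n",
              object@doublingTime, object@growthRate, object@v0,
              object@rSquared, object@nPoints))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: slope %.4g, R^2 = %.4f, p = %.4g (n = %d)\n",
              object@slope, object@rSquared, object@pValue, object@n))
})

# ---- accessors -------------------------------------------------------------

#' @rdname midTimes
#' @export
setMethod("midTimes", "FrameSchedule", function(x)
  (x@starts + x@durations / 2) / 60)

#' @rdname midTimes
#' @export
setMethod("midTimes", "DynamicImage", function(x) midTimes(x@schedule))

#' @rdname midTimes
#' @export
setMethod("midTimes", "TimeActivityCurve", function(x) x@midTimes)

#' @rdname midTimes
#' @export
setMethod("midTimes", "InputFunction", function(x) x@midTimes)

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@starts))

#' @rdname nFrames
#' @export
setMethod("nFrames", "DynamicImage", function(x) dim(x@values)[4L])

#' @rdname frameStarts
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@starts)

#' @rdname frameDurations
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)

#' @rdname schedule
#' @export
setMethod("schedule", "DynamicImage", function(x) x@schedule)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DynamicImage", function(x) x@spacing)

#' @rdname values
#' @export
setMethod("values", "DynamicImage", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "TimeActivityCurve", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "InputFunction", function(x) x@plasmaValues)

#' @rdname trueKi
#' @export
setMethod("trueKi", "KineticGroundTruth", function(x) {
  if (x@k3 == 0) 0 else x@K1 * x@k3 / (x@k2 + x@k3)
})
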