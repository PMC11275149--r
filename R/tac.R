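#' @include AllClasses.R imaging-io.R
NULL

#' Extract the time-activity curve of a VOI
#'
#' Per-frame unweighted mean over the member voxels of the named organ; the
#' curve lives on the schedule's frame mid-times.
#'
#' @param image a \code{\link{DynamicImage}}.
#' @param mask a \code{\link{VoiMask}} on the same grid.
#' @param organ VOI name defined in the mask.
#' @return a \code{\link{TimeActivityCurve}} in kBq/mL.
#' @export
extractTac <- function(image, mask, organ) {
  checkSameGrid(mask, image)
  idx <- .voiIndices(mask, organ)
  d <- dim(image@values)
  nspat <- prod(d[1:3])
  vm <- matrix(image@values, nrow = nspat)  # voxels x frames view
  vals <- colMeans(vm[idx, , drop = FALSE])
  new("TimeActivityCurve", midTimes = midTimes(image), values = vals,
      units = "kBq/mL", organ = organ, nVoxels = length(idx))
}

#' Convert a TAC to standardized uptake values
#'
#' Body-weight SUV with tissue density taken as 1 g/mL:
#' \deqn{SUV(t) = C(t) / (1000 \cdot A_{inj} / W)}
#' with C in kBq/mL, injected activity A_inj in MBq and body weight W in g.
#' The factor 1000 (MBq to kBq) is applied exactly here and nowhere else.
#'
#' @param tac a \code{\link{TimeActivityCurve}} in kBq/mL.
#' @param injectedActivity MBq (> 0).
#' @param bodyWeight g (> 0).
#' @return the TAC with unitless SUV values.
#' @export
tacToSuv <- function(tac, injectedActivity, bodyWeight) {
  if (tac@units != "kBq/mL")
    .err(sprintf("SUV conversion expects a kBq/mL curve, got %s", tac@units),
         "dynPET_unit_error")
  if (injectedActivity <= 0 || bodyWeight <= 0)
    .err("injected activity and body weight must be positive",
         "dynPET_parameter_error")
  norm <- 1000 * injectedActivity / bodyWeight
  new("TimeActivityCurve", midTimes = tac@midTimes, values = tac@values / norm,
      units = "SUV", organ = tac@organ, nVoxels = tac@nVoxels)
}

#' Area under a time-activity curve
#'
#' Trapezoidal integral on the mid-time grid between \code{t0} and
#' \code{t1} minutes, with a virtual (0, 0) anchor prepended (activity is
#' zero at injection). Bounds inside the grid are handled by linear
#' interpolation; past the last mid-time the curve is extended with the
#' last frame mean (frame means are constant over their frame, so this is
#' how a 0--60 min AUC reaches the end of the final frame).
#'
#' @param tac a \code{\link{TimeActivityCurve}}.
#' @param t0,t1 integration bounds in minutes, \code{t0 <= t1}.
#' @return the integral in kBq·min/mL (or SUV·min for SUV curves).
#' @export
tacAuc <- function(tac, t0 = 0, t1 = max(tac@midTimes)) {
  if (t0 > t1) .err("reversed integration bounds", "dynPET_argument_error")
  if (t0 == t1) return(0)
  tt <- c(0, tac@midTimes)
  vv <- c(0, tac@values)
  grid <- sort(unique(c(t0, t1, tt[tt >= t0 & tt <= t1])))
  y <- stats::approx(tt, vv, xout = grid, rule = 2)$y
  sum(diff(grid) * (y[-length(y)] + y[-1]) / 2)
}
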