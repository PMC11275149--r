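#' @include AllClasses.R synthetic-input.R frame-schedule.R
NULL

#' Two-tissue-compartment kinetic parameters
#'
#' @param K1 plasma-to-tissue transport, mL·min^-1·mL^-1.
#' @param k2 efflux rate, min^-1.
#' @param k3 trapping (phosphorylation) rate, min^-1; 0 gives a reversible
#'   tracer with zero net influx.
#' @param vb fractional blood volume in [0, 1).
#' @return a \code{\link{KineticGroundTruth}}.
#' @export
kineticGroundTruth <- function(K1, k2, k3, vb = 0) {
  new("KineticGroundTruth", K1 = K1, k2 = k2, k3 = k3, vb = vb)
}

# Fine grid (step <= maxStep min, <= 0.25 s over the first two minutes
# where the bolus curvature is high) whose points include every frame
# boundary, so per-frame trapezoid averages are well defined.
.fineGrid <- function(sched, maxStep = 1 / 60) {
  bounds <- c(sched@starts, sum(sched@durations)) / 60
  end <- max(bounds)
  tt <- seq(0, end, by = maxStep)
  early <- seq(0, min(2, end), by = 1 / 240)
  sort(unique(c(tt, early, bounds)))
}

# Trapezoid average of y(tt) over [a, b] for each frame.
.frameAverage <- function(tt, y, sched) {
  vapply(seq_along(sched@starts), function(i) {
    a <- sched@starts[i] / 60
    b <- (sched@starts[i] + sched@durations[i]) / 60
    idx <- which(tt >= a - 1e-9 & tt <= b + 1e-9)
    x <- tt[idx]; v <- y[idx]
    sum(diff(x) * (v[-length(v)] + v[-1]) / 2) / (b - a)
  }, numeric(1))
}

#' Simulate a frame-averaged tissue time-activity curve
#'
#' Integrates the irreversible two-tissue compartment model
#' \deqn{dC_1/dt = K_1 C_p(t) - (k_2 + k_3) C_1, \quad dC_2/dt = k_3 C_1}
#' on a fine internal grid (step <= 1 s) and returns the measured tissue
#' concentration \eqn{C_T = (1 - v_b)(C_1 + C_2) + v_b C_b} averaged over
#' each acquisition frame, i.e. what a reconstructed frame reports.
#'
#' @param gt a \code{\link{KineticGroundTruth}}.
#' @param plasmaFun function of time (minutes) returning plasma kBq/mL.
#' @param sched a \code{\link{FrameSchedule}}.
#' @param bloodFun function of time returning whole-blood kBq/mL; required
#'   when \code{vb > 0}.
#' @param organ VOI name recorded on the returned curve.
#' @return a \code{\link{TimeActivityCurve}} (nVoxels = 1) on the schedule's
#'   mid-times.
#' @export
simulateTissueTac <- function(gt, plasmaFun, sched, bloodFun = NULL,
                              organ = "tissue") {
  if (gt@vb > 0 && is.null(bloodFun))
    .err("vb > 0 requires a whole-blood curve (bloodFun)",
         "dynPET_parameter_error")
  tt <- .fineGrid(sched)
  beta <- gt@k2 + gt@k3
  deriv <- function(t, y, p)
    list(c(gt@K1 * plasmaFun(t) - beta * y[1], gt@k3 * y[1]))
  out <- deSolve::lsoda(c(C1 = 0, C2 = 0), tt, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  tissue <- (1 - gt@vb) * (out[, "C1"] + out[, "C2"])
  if (gt@vb > 0) tissue <- tissue + gt@vb * bloodFun(tt)
  new("TimeActivityCurve", midTimes = midTimes(sched),
      values = .frameAverage(tt, tissue, sched), units = "kBq/mL",
      organ = organ, nVoxels = 1L)
}

#' Frame-averaged curve of an arbitrary concentration function
#'
#' Averages \code{fun(t)} over each acquisition frame on a fine grid; used
#' to fill blood-pool phantom regions and to frame-average the simulated
#' input.
#'
#' @param fun function of time in minutes.
#' @param sched a \code{\link{FrameSchedule}}.
#' @return numeric per-frame means.
#' @export
frameAveragedCurve <- function(fun, sched) {
  tt <- .fineGrid(sched)
  .frameAverage(tt, fun(tt), sched)
}
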