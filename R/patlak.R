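#' @include AllClasses.R input-function.R
NULL

# Cumulative integral of a frame-mean curve from t = 0 to each frame
# mid-time: full preceding frames plus half the current frame. Exact when
# the frame means are exact; the (0, 0) anchor is implicit because frame 1
# starts at injection.
.frameCumInt <- function(vals, sched) {
  dm <- sched@durations / 60
  cumsum(dm * vals) - dm * vals / 2
}

#' Patlak variables of a tissue curve against a plasma input
#'
#' For each frame time T the graphical-analysis variables are
#' \deqn{x(T) = \int_0^T C_p dt / C_p(T) \quad (min), \qquad
#'       y(T) = C_{ROI}(T) / C_p(T)}
#' with the plasma integral taken from injection (t = 0). Frames with
#' mid-time below \code{tStar} are flagged excluded; the plot is treated as
#' linear from \code{tStar} on (10 min by default).
#'
#' The non-default \code{tissueIntegral = TRUE} replaces the ordinate's
#' tissue value with the tissue AUC from 0 to T. That reading is provided
#' for comparison only: it is not the standard linearization and does not
#' estimate Ki as a slope.
#'
#' @param tissueTac a \code{\link{TimeActivityCurve}}.
#' @param inputFn an \code{\link{InputFunction}} on the same time grid.
#' @param sched the \code{\link{FrameSchedule}} of both curves.
#' @param tStar linearity onset in minutes.
#' @param tissueIntegral use \eqn{\int_0^T C_{ROI} dt} in the ordinate
#'   (comparison only).
#' @return a \code{\link{PatlakPoints}}.
#' @export
patlakPoints <- function(tissueTac, inputFn, sched, tStar = 10,
                         tissueIntegral = FALSE) {
  if (!isTRUE(all.equal(tissueTac@midTimes, inputFn@midTimes)))
    .err("tissue TAC and input function must share the time grid",
         "dynPET_grid_mismatch")
  mt <- tissueTac@midTimes
  cp <- inputFn@plasmaValues
  include <- mt >= tStar
  if (sum(include) < 3L)
    .err(sprintf("only %d frame(s) at or after t* = %g min; need >= 3",
                 sum(include), tStar), "dynPET_insufficient_data")
  if (any(cp[include] <= 0))
    .err("plasma input is zero or negative at an included frame",
         "dynPET_degenerate_input")
  cumCp <- .frameCumInt(cp, sched)
  ct <- if (tissueIntegral) .frameCumInt(tissueTac@values, sched)
        else tissueTac@values
  ok <- cp > 0
  x <- ifelse(ok, cumCp / cp, NA_real_)
  y <- ifelse(ok, ct / cp, NA_real_)
  new("PatlakPoints", x = x, y = y, include = include & ok, tStar = tStar)
}

#' Ordinary least-squares Patlak fit
#'
#' Unweighted OLS of y on x over the included points. The slope is the net
#' influx rate Ki (mL·min^-1·mL^-1), the intercept is Int. A zero-variance
#' ordinate is reported as Ki = 0, Int = y, R^2 = 0 with the degenerate
#' flag set.
#'
#' @param points a \code{\link{PatlakPoints}}.
#' @return a \code{\link{PatlakResult}}.
#' @export
patlakFit <- function(points) {
  x <- points@x[points@include]
  y <- points@y[points@include]
  if (length(unique(x)) == 1L)
    .err("all abscissa values identical; Patlak fit is singular",
         "dynPET_singular_fit")
  if (stats::var(y) == 0)
    return(new("PatlakResult", Ki = 0, intercept = y[1], rSquared = 0,
               tStar = points@tStar, nPoints = length(x), degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # quiet on exact fits
  new("PatlakResult", Ki = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = sm$r.squared, tStar = points@tStar,
      nPoints = length(x), degenerate = FALSE)
}

#' One-call Patlak estimate
#'
#' \code{\link{patlakPoints}} followed by \code{\link{patlakFit}}.
#'
#' @inheritParams patlakPoints
#' @return a \code{\link{PatlakResult}}.
#' @export
patlakEstimate <- function(tissueTac, inputFn, sched, tStar = 10) {
  patlakFit(patlakPoints(tissueTac, inputFn, sched, tStar))
}
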