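#' @include AllClasses.R
NULL

#' Feng-type plasma model parameters
#'
#' Defaults describe a mouse-like bolus: a sharp first-pass peak well inside
#' the first two minutes (lambda1), a fast distribution phase that has
#' essentially cleared by 10 min (lambda2, half-life about 1.5 min) and a
#' slow terminal clearance (lambda3), so that by the 10-minute linearity
#' onset used in the graphical analysis the input tail is effectively
#' mono-exponential. The plasma-to-blood equilibrium ratio rises from r0 at
#' injection to rEq with time constant tauR.
#'
#' @param A1 kBq·mL^-1·min^-1; \code{A2,A3} kBq/mL.
#' @param A2,A3 amplitudes, kBq/mL.
#' @param lambda1,lambda2,lambda3 decay rates, min^-1 (strictly decreasing).
#' @param r0,rEq plasma-to-blood ratio at t = 0 and at equilibrium.
#' @param tauR ratio time constant, minutes.
#' @return an \code{\link{InputModelParams}}.
#' @export
inputModelParams <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                             lambda1 = 4.13, lambda2 = 0.45, lambda3 = 0.012,
                             r0 = 1.0, rEq = 1.2, tauR = 5) {
  new("InputModelParams", A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
      lambda2 = lambda2, lambda3 = lambda3, r0 = r0, rEq = rEq, tauR = tauR)
}

#' Evaluate the Feng plasma input
#'
#' \eqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#' + A_3 e^{-\lambda_3 t}}, clipped at zero; \eqn{C_p(0) = 0} by
#' construction.
#'
#' @param params an \code{\link{InputModelParams}}.
#' @param times minutes, nonnegative and nondecreasing.
#' @return plasma activity concentration, kBq/mL.
#' @export
fengPlasmaInput <- function(params, times) {
  if (any(times < 0)) .err("times must be nonnegative", "dynPET_parameter_error")
  if (is.unsorted(times)) .err("times must be nondecreasing", "dynPET_parameter_error")
  with_p <- function(t)
    (params@A1 * t - params@A2 - params@A3) * exp(-params@lambda1 * t) +
      params@A2 * exp(-params@lambda2 * t) + params@A3 * exp(-params@lambda3 * t)
  pmax(0, with_p(times))
}

#' Plasma-to-blood equilibrium ratio
#'
#' \eqn{r(t) = r_{eq} + (r_0 - r_{eq}) e^{-t/\tau_r}}: plasma concentration
#' equals whole-blood concentration times r(t). FDG equilibrates between
#' plasma and erythrocytes over the first minutes, so r drifts from its
#' injection value toward a constant.
#'
#' @param params an \code{\link{InputModelParams}}.
#' @param times minutes.
#' @return unitless ratio values, all positive (error otherwise).
#' @export
plasmaToBloodRatio <- function(params, times) {
  r <- params@rEq + (params@r0 - params@rEq) * exp(-times / params@tauR)
  if (any(r <= 0))
    .err("plasma-to-blood ratio must stay positive", "dynPET_parameter_error")
  r
}

#' Whole-blood curve from a plasma curve
#'
#' \code{blood(t) = plasma(t) / r(t)}; the exact inverse of
#' \code{\link{plasmaInputFromBlood}} under the same parameters.
#'
#' @param plasma numeric plasma concentrations, kBq/mL.
#' @param times minutes, same length.
#' @param params an \code{\link{InputModelParams}} providing the ratio.
#' @return whole-blood concentrations, kBq/mL.
#' @export
bloodFromPlasma <- function(plasma, times, params) {
  plasma / plasmaToBloodRatio(params, times)
}
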