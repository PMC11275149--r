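#' @include AllClasses.R synthetic-input.R tac.R
NULL

#' Scale the vena-cava curve to the liver curve
#'
#' The whole-blood image-derived input is recovered by scaling the
#' vena-cava TAC so its last-frame value matches the liver last-frame
#' value: \code{scaleFactor = liver(T_last) / vc(T_last)}. The last time
#' frame means exactly that -- the final frame's mean value, with no tail
#' fitting or smoothing. Negative TAC values (possible after reconstruction
#' corrections) are clipped to zero first, with a message reporting the
#' count.
#'
#' @param vcTac vena-cava \code{\link{TimeActivityCurve}} (kBq/mL).
#' @param liverTac liver TAC on the identical time grid.
#' @return list with \code{blood} (the scaled whole-blood TAC) and
#'   \code{scaleFactor}.
#' @export
scaleVenaCavaToLiver <- function(vcTac, liverTac) {
  if (!isTRUE(all.equal(vcTac@midTimes, liverTac@midTimes)))
    .err("vena-cava and liver TACs must share the time grid",
         "dynPET_grid_mismatch")
  nneg <- sum(vcTac@values < 0) + sum(liverTac@values < 0)
  if (nneg > 0)
    message(sprintf("clipped %d negative TAC value(s) to zero before scaling",
                    nneg))
  vc <- pmax(vcTac@values, 0)
  lv <- pmax(liverTac@values, 0)
  n <- length(vc)
  if (vc[n] <= 0)
    .err("vena-cava last-frame value must be positive for scaling",
         "dynPET_degenerate_input")
  sf <- lv[n] / vc[n]
  blood <- new("TimeActivityCurve", midTimes = vcTac@midTimes,
               values = vc * sf, units = "kBq/mL", organ = "whole_blood",
               nVoxels = vcTac@nVoxels)
  list(blood = blood, scaleFactor = sf)
}

#' Plasma input function from a whole-blood curve
#'
#' Applies the time-dependent plasma-to-blood equilibrium ratio:
#' \code{plasma(t) = blood(t) * r(t)} with
#' \eqn{r(t) = r_{eq} + (r_0 - r_{eq}) e^{-t/\tau_r}}. Exact inverse of
#' \code{\link{bloodFromPlasma}} under the same parameters.
#'
#' @param bloodTac whole-blood \code{\link{TimeActivityCurve}}.
#' @param ratioParams an \code{\link{InputModelParams}} (only the ratio
#'   fields are used).
#' @param scaleFactor provenance: the vena-cava-to-liver factor already
#'   applied to the blood curve (recorded, not re-applied).
#' @return an \code{\link{InputFunction}}.
#' @export
plasmaInputFromBlood <- function(bloodTac, ratioParams, scaleFactor = 1) {
  r <- plasmaToBloodRatio(ratioParams, bloodTac@midTimes)
  new("InputFunction", midTimes = bloodTac@midTimes,
      plasmaValues = bloodTac@values * r, scaleFactor = scaleFactor,
      ratioParams = list(r0 = ratioParams@r0, rEq = ratioParams@rEq,
                         tauR = ratioParams@tauR))
}

#' Build the image-derived plasma input function
#'
#' Convenience composition of the two IDIF steps: scale the vena-cava TAC
#' to the liver TAC at the last frame, then convert the whole-blood curve
#' to plasma with the equilibrium ratio.
#'
#' @param vcTac,liverTac TACs in kBq/mL on the same grid.
#' @param ratioParams an \code{\link{InputModelParams}}.
#' @return an \code{\link{InputFunction}} with full provenance.
#' @export
buildPlasmaInput <- function(vcTac, liverTac, ratioParams = inputModelParams()) {
  sc <- scaleVenaCavaToLiver(vcTac, liverTac)
  plasmaInputFromBlood(sc$blood, ratioParams, scaleFactor = sc$scaleFactor)
}
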