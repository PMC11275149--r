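#' @include AllClasses.R
NULL

#' Organ lumped constants
#'
#' The FDG-to-glucose conversion factors used for MRGlu: 1 for tumor,
#' 0.625 for brain, 0.67 for heart.
#'
#' @return named numeric vector.
#' @export
lumpedConstants <- function() c(tumor = 1, brain = 0.625, heart = 0.67)

#' Scan-average blood glucose
#'
#' Arithmetic mean of the measurements at the beginning and the end of the
#' scan; a missing post-scan value falls back to the pre-scan value with a
#' warning.
#'
#' @param pre,post blood glucose, mmol/L (> 0; post may be NA).
#' @return mmol/L.
#' @export
averageBloodGlucose <- function(pre, post = NA_real_) {
  if (is.na(pre) && is.na(post))
    .err("no blood glucose measurement available", "dynPET_missing_data")
  if (is.na(post)) {
    warning("post-scan glucose missing; using the pre-scan value")
    return(pre)
  }
  if (pre <= 0 || post <= 0)
    .err("blood glucose must be positive", "dynPET_parameter_error")
  (pre + post) / 2
}

#' Metabolic rate of glucose from the net influx rate
#'
#' \deqn{MRGlu = \frac{C_{glu}}{LC} K_i}
#' with Cglu in mmol/L (numerically equal to umol/mL) and the organ's
#' lumped constant LC, giving MRGlu in umol·min^-1·mL^-1.
#'
#' @param ki net influx rate, mL·min^-1·mL^-1 (or a
#'   \code{\link{PatlakResult}}).
#' @param cgluMean scan-average blood glucose, mmol/L.
#' @param organ one of \code{names(lumpedConstants())}; ignored when
#'   \code{lc} is supplied.
#' @param lc explicit lumped constant overriding the organ lookup.
#' @return a \code{\link{MetabolicResult}}.
#' @export
metabolicRateGlucose <- function(ki, cgluMean, organ = NULL, lc = NULL) {
  if (is(ki, "PatlakResult")) ki <- ki@Ki
  if (is.null(lc)) {
    if (is.null(organ) || !organ %in% names(lumpedConstants()))
      .err(sprintf("no lumped constant known for organ '%s'; supply lc",
                   if (is.null(organ)) "<none>" else organ),
           "dynPET_lookup_error")
    lc <- lumpedConstants()[[organ]]
  }
  if (is.null(organ)) organ <- "custom"
  new("MetabolicResult", mrglu = cgluMean * ki / lc, Ki = ki,
      cgluMean = cgluMean, lumpedConstant = lc, organ = organ)
}

#' Glucose-corrected SUV
#'
#' \code{SUVglu = SUV x Cglu}: the semiquantitative uptake value multiplied
#' by the scan-average blood glucose (mmol/L). Vectorized.
#'
#' @param suv unitless SUV (>= 0).
#' @param cgluMean blood glucose, mmol/L (>= 0).
#' @return SUV·mmol/L.
#' @export
suvGlu <- function(suv, cgluMean) {
  if (any(suv < 0) || any(cgluMean < 0))
    .err("SUV and glucose must be nonnegative", "dynPET_parameter_error")
  suv * cgluMean
}
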