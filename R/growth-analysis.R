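#' @include AllClasses.R
NULL

#' Log-linear doubling-time fit
#'
#' OLS of ln(volume) on day for one animal (or pooled means): the slope is
#' the growth rate (day^-1) and the doubling time is ln(2)/slope. A
#' nonpositive fitted slope yields an infinite doubling time (no growth).
#'
#' @param records data.frame with columns \code{day} and \code{volume}
#'   (mm^3, > 0); at least two distinct days.
#' @return a \code{\link{GrowthFit}}.
#' @export
fitDoublingTime <- function(records) {
  if (any(records$volume <= 0))
    .err("volumes must be positive for a log-linear fit",
         "dynPET_parameter_error")
  if (length(unique(records$day)) < 2L)
    .err("need >= 2 distinct days", "dynPET_insufficient_data")
  fit <- stats::lm(log(volume) ~ day, data = records)
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # quiet on exact fits
  if (is.nan(r2)) r2 <- 1  # two points: exact fit
  new("GrowthFit",
      doublingTime = if (slope > 0) log(2) / slope else Inf,
      growthRate = slope, v0 = exp(unname(stats::coef(fit)[1])),
      rSquared = r2, nPoints = nrow(records))
}

#' Per-animal doubling times of a cohort
#'
#' Applies \code{\link{fitDoublingTime}} to each subject and returns the
#' per-animal estimates (the cohort summary is their mean, the usual
#' convention when the fitting method is per animal).
#'
#' @param cohort data.frame with columns subject_id, day, volume.
#' @return data.frame with subject_id, doubling_time, growth_rate,
#'   r_squared.
#' @export
cohortDoublingTimes <- function(cohort) {
  subjects <- unique(cohort$subject_id)
  fits <- lapply(subjects, function(s)
    fitDoublingTime(cohort[cohort$subject_id == s, , drop = FALSE]))
  data.frame(subject_id = subjects,
             doubling_time = vapply(fits, function(f) f@doublingTime, 1),
             growth_rate = vapply(fits, function(f) f@growthRate, 1),
             r_squared = vapply(fits, function(f) f@rSquared, 1))
}
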