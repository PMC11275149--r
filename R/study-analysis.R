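#' @include AllClasses.R
NULL

#' Regress a kinetic metric on blood glucose
#'
#' Simple linear regression of a metric (Ki, MRGlu, SUV, ...) on blood
#' glucose across scans, with R^2 and the two-sided t-test of slope = 0 --
#' the screen used to decide which outcome metric is glucose-independent.
#'
#' @param glucose mmol/L, length n >= 3, nonconstant.
#' @param metric metric values, same length, finite.
#' @return a \code{\link{CorrelationResult}}.
#' @export
regressMetricOnGlucose <- function(glucose, metric) {
  if (length(glucose) != length(metric) || length(glucose) < 3L)
    .err("need >= 3 paired observations", "dynPET_insufficient_data")
  if (any(!is.finite(glucose)) || any(!is.finite(metric)))
    .err("values must be finite", "dynPET_parameter_error")
  if (stats::var(glucose) == 0)
    .err("glucose has zero variance; regression is singular",
         "dynPET_singular_fit")
  fit <- stats::lm(metric ~ glucose)
  sm <- suppressWarnings(summary(fit))  # quiet on exact fits
  new("CorrelationResult", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = sm$r.squared,
      pValue = unname(sm$coefficients[2, 4]),
      n = length(glucose))
}

#' Per-week, per-organ summary of tidy metric records
#'
#' Mean, SD (n-1 denominator), coefficient of variation (SD/mean) and n for
#' every (week, organ, metric) stratum of a tidy record table. Empty strata
#' simply yield no row.
#'
#' @param records data.frame with columns week, organ, metric, value (a
#'   subject column is allowed and ignored).
#' @return data.frame with week, organ, metric, n, mean, sd, cv, ordered by
#'   (week, organ, metric).
#' @export
weeklySummary <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(week = integer(), organ = character(),
                      metric = character(), n = integer(), mean = numeric(),
                      sd = numeric(), cv = numeric()))
  key <- interaction(records$week, records$organ, records$metric, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    m <- mean(g$value)
    s <- if (nrow(g) > 1L) stats::sd(g$value) else 0
    data.frame(week = g$week[1], organ = g$organ[1], metric = g$metric[1],
               n = nrow(g), mean = m, sd = s,
               cv = if (m != 0) s / m else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$week, out$organ, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  out
}
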