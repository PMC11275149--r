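# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the tissue oracle is the closed-form
# convolution solution of the irreversible 2TC model for a Feng input
# (no ODE solver), and integrals are analytic.

# Analytic Feng curve and its running integral (no zero-clipping needed for
# the parameter sets used in tests; asserted where it matters).
fengOracle <- function(t, p) {
  (p@A1 * t - p@A2 - p@A3) * exp(-p@lambda1 * t) +
    p@A2 * exp(-p@lambda2 * t) + p@A3 * exp(-p@lambda3 * t)
}

fengIntOracle <- function(t, p) {
  p@A1 * (1 - exp(-p@lambda1 * t) * (1 + p@lambda1 * t)) / p@lambda1^2 -
    (p@A2 + p@A3) * (1 - exp(-p@lambda1 * t)) / p@lambda1 +
    p@A2 * (1 - exp(-p@lambda2 * t)) / p@lambda2 +
    p@A3 * (1 - exp(-p@lambda3 * t)) / p@lambda3
}

# Convolution of the Feng input with exp(-beta t), term by term:
#   a e^{-l t} * e^{-b t}      = a (e^{-l t} - e^{-b t}) / (b - l)
#   A1 t e^{-l1 t} * e^{-b t}  = A1 [ t e^{-l1 t} / mu - (e^{-l1 t} - e^{-b t}) / mu^2 ],
# with mu = b - l1.
fengConvOracle <- function(t, p, beta) {
  stopifnot(abs(beta - p@lambda1) > 1e-9, abs(beta - p@lambda2) > 1e-9,
            abs(beta - p@lambda3) > 1e-9)
  mu <- beta - p@lambda1
  ramp <- p@A1 * (t * exp(-p@lambda1 * t) / mu -
                    (exp(-p@lambda1 * t) - exp(-beta * t)) / mu^2)
  expTerm <- function(a, l)
    a * (exp(-l * t) - exp(-beta * t)) / (beta - l)
  ramp + expTerm(-(p@A2 + p@A3), p@lambda1) +
    expTerm(p@A2, p@lambda2) + expTerm(p@A3, p@lambda3)
}

# Closed-form instantaneous tissue concentration (vb = 0):
#   C_T(t) = Ki * int_0^t Cp + (k2/beta) * K1 * (Cp conv e^{-beta t}),
# an exact identity for the irreversible 2TC model.
tissueOracle <- function(t, p, K1, k2, k3) {
  beta <- k2 + k3
  ki <- if (k3 == 0) 0 else K1 * k3 / beta
  ki * fengIntOracle(t, p) + (k2 / beta) * K1 * fengConvOracle(t, p, beta)
}

# Frame average of a closed-form curve by dense trapezoid (independent of
# the package's internal grid/averaging code).
frameAvgOracle <- function(fun, sched, nSub = 400) {
  st <- frameStarts(sched) / 60
  du <- frameDurations(sched) / 60
  vapply(seq_along(st), function(i) {
    tt <- seq(st[i], st[i] + du[i], length.out = nSub)
    y <- fun(tt)
    sum(diff(tt) * (y[-length(y)] + y[-1]) / 2) / du[i]
  }, numeric(1))
}

# Small, fast phantom used by several files.
smallPhantomConfig <- function(noiseScale = 0) {
  phantomConfig(gridDim = c(32, 32, 48), noiseScale = noiseScale)
}

# A TimeActivityCurve literal.
makeTac <- function(times, vals, organ = "test", units = "kBq/mL",
                    nVoxels = 1L) {
  new("TimeActivityCurve", midTimes = times, values = vals, units = units,
      organ = organ, nVoxels = nVoxels)
}

# An InputFunction literal.
makeInput <- function(times, vals, scaleFactor = 1) {
  new("InputFunction", midTimes = times, plasmaValues = vals,
      scaleFactor = scaleFactor, ratioParams = list())
}
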