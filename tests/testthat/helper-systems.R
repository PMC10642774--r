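# Small fixture systems built in code, plus independent closed-form
# oracles used to validate the matrix-exponential machinery.

onePool <- function(k = 1, u = 1) compartmentalSystem(u, matrix(-k))

# serial two-pool chain: input to pool 1 (rate a), transfer b to pool 2
# (rate c); hand-derived phase-type density used as an independent oracle
twoPoolSerial <- function(a = 2, b = 1, c = 0.25) {
  compartmentalSystem(u = c(1, 0),
                      B = matrix(c(-a, 0, b, -c), 2, 2, byrow = TRUE))
}

# f_T for twoPoolSerial, derived by hand from the absorbing chain:
# exit from pool 1 at rate (a-b), or transfer (prob b/a) then Exp(c)
twoPoolSerialTT <- function(tau, a = 2, b = 1, c = 0.25) {
  (a - b) * exp(-a * tau) + b * c * (exp(-c * tau) - exp(-a * tau)) / (a - c)
}

emanuel <- emanuelModel()

# analytic transit-time CDF (closed form, shared by several tests)
ttCDF <- function(sys) {
  function(q) {
    sapply(q, function(a) {
      if (a <= 0) return(0)
      1 - sum(as.matrix(Matrix::expm(a * compartmentalMatrix(sys))) %*%
                inputVector(sys)) / sum(inputVector(sys))
    })
  }
}

# exit-age CDF of particles leaving a forced system inside a window:
# the respiration-weighted average of the BTT CDFs across the window
windowBTTCDF <- function(tds, window, ages, nQuad = 11) {
  tq <- seq(window[1], window[2], length.out = nQuad)
  btts <- lapply(tq, function(t) bttDistribution(tds, t, ages = ages,
                                                 keepMass = FALSE))
  w <- vapply(btts, `[[`, 0, "totalRespiration")
  w <- w * c(0.5, rep(1, nQuad - 2), 0.5)  # trapezoid in time
  w <- w / sum(w)
  cdfs <- vapply(btts, function(b) {
    cumsum(c(0, diff(b$ages) * (head(b$density, -1) +
                                tail(b$density, -1)) / 2)) /
      b$totalRespiration
  }, numeric(length(ages)))
  avg <- as.numeric(cdfs %*% w)
  function(q) approx(ages, avg, xout = q, rule = 2)$y
}
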