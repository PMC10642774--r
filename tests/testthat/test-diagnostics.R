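test_that("homogeneity ratios are exact for exponential and one-pool systems", {
  k <- 0.3
  expect_equal(homogeneityH(log(2) / k, 1 / k), 1)
  expect_error(homogeneityH(1, 0), "> 0")
  expect_error(homogeneityHPrime(1, -2), "> 0")

  tds <- timeDependentSystem(onePool(k), t0 = 0)
  b <- bttDistribution(tds, 5, ages = seq(0, 60, 0.01), keepMass = FALSE)
  EA <- meanSystemAge(tds, 5, ages = seq(0, 60, 0.01))
  expect_equal(homogeneityH(b$median, b$mean), 1, tolerance = 1e-3)
  expect_equal(homogeneityHPrime(b$mean, EA), 1, tolerance = 1e-6)
})

test_that("h declines as a slow mixture component gains weight", {
  # two-pool parallel family: fast pool fixed, slow pool's input grows
  h <- sapply(c(0.01, 0.05, 0.1, 0.2), function(w) {
    sys <- compartmentalSystem(c(1 - w, w),
                               matrix(c(-1, 0, 0, -0.01), 2, 2))
    mom <- transitTimeMoments(sys)
    homogeneityH(transitTimeQuantile(sys, 0.5), mom$mean)
  })
  expect_true(all(diff(h) < 0))
  expect_lt(h[4], 1)
})

test_that("aggregation conserves respiration and averages means linearly", {
  ages <- seq(0, 600, by = 0.05)
  fast <- equilibriumBTT(compartmentalSystem(10, matrix(-0.5)),
                         ages = ages)
  slow <- equilibriumBTT(compartmentalSystem(10, matrix(-0.05)),
                         ages = ages)

  # identity and doubling
  one <- aggregateBTT(list(fast))
  expect_equal(one$pdf, fast$pdf)
  expect_equal(one$mean, fast$mean)
  two <- aggregateBTT(list(fast, fast))
  expect_equal(two$totalRespiration, 2 * fast$totalRespiration)
  expect_equal(two$pdf, fast$pdf, tolerance = 1e-12)
  expect_equal(two$median, fast$median, tolerance = 1e-12)

  # equal-respiration fast+slow mixture: brute-force mixture oracle
  mix <- aggregateBTT(list(fast, slow))
  expect_equal(mix$totalRespiration,
               fast$totalRespiration + slow$totalRespiration,
               tolerance = 1e-12)
  expect_equal(mix$mean, (fast$mean + slow$mean) / 2, tolerance = 1e-10)
  # mixture CDF: 0.5 F_fast + 0.5 F_slow; median from the closed forms
  medOracle <- uniroot(function(q)
    0.5 * (1 - exp(-0.5 * q)) + 0.5 * (1 - exp(-0.05 * q)) - 0.5,
    c(0, 100), tol = 1e-10)$root
  expect_equal(mix$median, medOracle, tolerance = 1e-3)
  expect_gt(mix$median, fast$median)
  expect_lt(mix$median, slow$median)
  # closer to the fast member's median than the slow one's
  expect_lt(mix$median - fast$median, slow$median - mix$median)

  # mismatched grids and times are refused, never resampled silently
  other <- equilibriumBTT(compartmentalSystem(10, matrix(-0.5)),
                          ages = seq(0, 600, by = 0.1))
  expect_error(aggregateBTT(list(fast, other)), "age grid")
})
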