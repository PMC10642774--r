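test_that("one-pool distributions reduce to the exponential closed forms", {
  k <- 0.4
  sys <- onePool(k)
  ages <- seq(0, 40, by = 0.05)

  f0 <- poolAgeDensity(sys, ages = ages)
  expect_equal(as.numeric(f0$values), k * exp(-k * ages),
               tolerance = 1e-10)  # (X*)^-1 e^{aB} u = k e^{-ka}

  fA <- systemAgeDensity(sys, ages = ages)
  fT <- transitTimeDensity(sys, ages = ages)
  expect_equal(fA$values, k * exp(-k * ages), tolerance = 1e-10)
  expect_equal(fT$values, fA$values, tolerance = 1e-12)

  mom <- transitTimeMoments(sys)
  expect_equal(mom$mean, 1 / k, tolerance = 1e-12)
  expect_equal(mom$sd, 1 / k, tolerance = 1e-12)
  expect_equal(transitTimeQuantile(sys, 0.5), log(2) / k,
               tolerance = 1e-8)
})

test_that("two-pool serial chain matches the hand-derived phase-type density", {
  sys <- twoPoolSerial(a = 2, b = 1, c = 0.25)
  taus <- seq(0, 30, by = 0.1)
  ft <- transitTimeDensity(sys, ages = taus)
  expect_equal(ft$values, twoPoolSerialTT(taus), tolerance = 1e-9)
  # decomposition attributes release to the right pools and sums to f_T
  expect_equal(colSums(ft$byPool), ft$values, tolerance = 1e-12)
  # at age 0 all density comes from pool 1: release rate (a-b) times u
  expect_equal(unname(ft$byPool[1, 1]), 2 - 1)
})

test_that("age and transit-time pdfs normalize on default grids for random systems", {
  for (seed in 1:20) {
    n <- 2 + seed %% 3
    sys <- randomSystem(n, seed = seed)
    ages <- makeAgeGrid(sys)
    fT <- transitTimeDensity(sys, ages)
    fA <- systemAgeDensity(sys, ages = ages)
    intT <- trapz(ages, fT$values)
    intA <- trapz(ages, fA$values)
    expect_lt(abs(intT - 1), 1e-4)
    expect_lt(abs(intA - 1), 1e-4)
    expect_true(all(fT$values >= 0) && all(fA$values >= 0))
    # per-pool densities are defined only when every pool holds stock
    if (all(steadyState(sys)$x_star > 0)) {
      f0 <- poolAgeDensity(sys, ages = ages)
      for (i in seq_len(n))
        expect_lt(abs(trapz(ages, f0$values[i, ]) - 1), 2e-4)
      expect_true(all(f0$values >= 0))
    } else {
      expect_error(poolAgeDensity(sys, ages = ages), "zero stock")
    }
  }
})

test_that("mean transit time equals stock over input and the numeric integral", {
  for (seed in 21:30) {
    sys <- randomSystem(2 + seed %% 3, seed = seed)
    ss <- steadyState(sys)
    mom <- transitTimeMoments(sys)
    # exact steady-state identity between the two closed forms
    expect_equal(mom$mean, ss$total_stock / ss$total_input,
                 tolerance = 1e-10)
  }
  # numeric-integral route for the five-pool model
  ages <- makeAgeGrid(emanuel, tail_tol = 1e-8)
  ft <- transitTimeDensity(emanuel, ages)
  expect_equal(trapz(ages, ages * ft$values),
               transitTimeMoments(emanuel)$mean, tolerance = 1e-3)
})

test_that("five-pool equilibrium summaries and pool ordering are as expected", {
  mom <- transitTimeMoments(emanuel)
  expect_equal(mom$mean, 1760 / 113, tolerance = 1e-12)
  expect_equal(mom$sd, 45.012, tolerance = 1e-4)
  expect_equal(transitTimeQuantile(emanuel, 0.5), 2.2934,
               tolerance = 1e-4)
  expect_equal(transitTimeQuantile(emanuel, 0.95), 76.979,
               tolerance = 1e-4)
  # CDF(mean) > 0.5: right-skewed, median below mean
  expect_lt(transitTimeQuantile(emanuel, 0.5), mom$mean)

  # slowest pool dominates pool ages: mean age of soil >> non-woody parts
  ages <- makeAgeGrid(emanuel, tail_tol = 1e-6)
  f0 <- poolAgeDensity(emanuel, ages = ages)
  meanAges <- apply(f0$values, 1, function(v) trapz(ages, ages * v))
  expect_gt(meanAges["active_soil"], 50 * meanAges["nonwoody_tree"])

  # closed-form system-age mean vs numeric integral
  ss <- steadyState(emanuel)
  eaClosed <- sum(solve(-compartmentalMatrix(emanuel), ss$x_star)) /
    ss$total_stock
  fA <- systemAgeDensity(emanuel, ss, ages)
  expect_equal(trapz(ages, ages * fA$values), eaClosed, tolerance = 1e-3)
})

test_that("transit-time quantiles are strictly increasing and reject bad alpha", {
  alphas <- c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)
  qs <- transitTimeQuantile(emanuel, alphas)
  expect_true(all(diff(qs) > 0))
  expect_error(transitTimeQuantile(emanuel, 0), "alpha")
  expect_error(transitTimeQuantile(emanuel, 1), "alpha")
  expect_error(transitTimeQuantile(emanuel, -0.2), "alpha")
})
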