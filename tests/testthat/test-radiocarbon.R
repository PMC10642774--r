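test_that("atmospheric curves interpolate, extrapolate constantly and round-trip", {
  flat <- atmosphericC14Curve(c(1850, 1950), c(0, 0))
  expect_equal(atmDelta14C(flat, c(1800, 1900, 2000)), c(0, 0, 0))

  ramp <- atmosphericC14Curve(c(1950, 1960), c(0, 100))
  expect_equal(atmDelta14C(ramp, 1955), 50)
  expect_equal(fractionModern(ramp, 1960), 1.1)

  expect_error(atmosphericC14Curve(c(1950, 1950), c(0, 1)), "increasing")

  path <- withr::local_tempfile(fileext = ".csv")
  bomb <- syntheticBombCurve()
  writeAtmC14Curve(bomb, path)
  back <- readAtmC14Curve(path)
  expect_equal(back$years, bomb$years)
  expect_equal(back$delta14c, bomb$delta14c)
  expect_equal(back$zone, bomb$zone)

  # parse errors name the offending content
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(year = c(1950, 1940), delta14c = c(0, 1)), bad,
            row.names = FALSE)
  expect_error(readAtmC14Curve(bad), "row 2")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(year = 1950, value = 0), bad2, row.names = FALSE)
  expect_error(readAtmC14Curve(bad2), "delta14c")
})

test_that("synthetic bomb curve has plateau, peak placement and tunable decline", {
  bomb <- syntheticBombCurve(suessSlope = 0)
  expect_equal(atmDelta14C(bomb, 1900), 0)
  expect_equal(bomb$years[which.max(bomb$delta14c)], 1964)
  expect_equal(max(bomb$delta14c), 700)

  faster <- syntheticBombCurve(declineRate = 0.12, suessSlope = 0)
  yrs <- 1965:2020
  expect_true(all(atmDelta14C(faster, yrs) < atmDelta14C(bomb, yrs)))
  expect_error(syntheticBombCurve(peakValue = -5), "peakValue")
})

test_that("one-pool radiocarbon steady state matches F = k/(k+lambda)", {
  k <- 0.1
  lam <- log(2) / 5730
  sys <- onePool(k)
  tds <- timeDependentSystem(sys, t0 = 0)
  flat <- atmosphericC14Curve(c(0, 400), c(0, 0))
  run <- solveRadiocarbon(tds, flat, seq(0, 400, by = 50), lambda = lam)
  Fresp <- 1 + run$deltaResp / 1000
  expect_equal(Fresp, rep(k / (k + lam), length(Fresp)),
               tolerance = 1e-8)
  expect_true(all(run$deltaResp < 0))  # decay only under a 0-permil sky

  # lambda -> 0 degenerates the tracer to bulk carbon exactly
  run0 <- solveRadiocarbon(tds, flat, seq(0, 400, by = 50), lambda = 0)
  expect_equal(unname(run0$x14), unname(run0$x), tolerance = 1e-9)
})

test_that("respired Delta14C is bracketed by pool values and lags the bomb peak", {
  bomb <- syntheticBombCurve()
  tds <- timeDependentSystem(emanuel, t0 = 1850)
  times <- seq(1850, 2020, by = 1)
  run <- solveRadiocarbon(tds, bomb, times)

  # flux-weighted average property at every time
  for (i in seq(1, length(times), by = 10)) {
    expect_gte(run$deltaResp[i], min(run$deltaPools[i, ]) - 1e-9)
    expect_lte(run$deltaResp[i], max(run$deltaPools[i, ]) + 1e-9)
  }

  # the transit-time kernel delays and damps the atmospheric spike
  peakAtm <- times[which.max(atmDelta14C(bomb, times))]
  peakResp <- times[which.max(run$deltaResp)]
  expect_gt(peakResp, peakAtm)
  expect_lt(max(run$deltaResp), max(atmDelta14C(bomb, times)))

  # with the cycle at equilibrium, pools with slower turnover are more
  # depleted before the bomb era
  expect_lt(run$deltaPools[1, "active_soil"],
            run$deltaPools[1, "nonwoody_tree"])
})

test_that("scenario-minus-equilibrium differences vanish without forcing", {
  bomb <- syntheticBombCurve()
  times <- seq(1850, 1990, by = 1)
  ref <- solveRadiocarbon(timeDependentSystem(emanuel, t0 = 1850), bomb,
                          times)
  same <- solveRadiocarbon(globalChangeForcing(emanuel, FALSE, FALSE),
                           bomb, times)
  d <- scenarioDeltaDifference(same, ref)
  expect_lt(max(abs(d$deltaDiff)), 1e-8)
  short <- solveRadiocarbon(timeDependentSystem(emanuel, t0 = 1850),
                            bomb, seq(1850, 1900))
  expect_error(scenarioDeltaDifference(short, ref), "time grid")
})
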