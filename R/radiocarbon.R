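#' Atmospheric radiocarbon history
#'
#' A tabulated Delta-14C history (per mil) over calendar years, queried
#' by linear interpolation with constant extrapolation before the first
#' and after the last tabulated year.  \code{fractionModern()} converts
#' to the fraction-modern forcing \eqn{F = 1 + \Delta^{14}C/1000}.
#'
#' @param years strictly increasing calendar years.
#' @param delta14c Delta-14C values (per mil).
#' @param zone optional label (e.g. \code{"NH"}).
#' @return An object of class \code{"AtmosphericC14Curve"}; calling it
#'   is not supported, use \code{atmDelta14C(curve, t)}.
#' @export
atmosphericC14Curve <- function(years, delta14c, zone = "NH") {
  if (length(years) != length(delta14c))
    stop("years and delta14c must have equal length", call. = FALSE)
  if (any(diff(years) <= 0))
    stop("years must be strictly increasing", call. = FALSE)
  structure(list(years = as.numeric(years),
                 delta14c = as.numeric(delta14c), zone = zone),
            class = "AtmosphericC14Curve")
}

#' @rdname atmosphericC14Curve
#' @param curve an \code{AtmosphericC14Curve}.
#' @param t query times (yr).
#' @export
atmDelta14C <- function(curve, t) {
  stats::approx(curve$years, curve$delta14c, xout = t, rule = 2)$y
}

#' @rdname atmosphericC14Curve
#' @export
fractionModern <- function(curve, t) 1 + atmDelta14C(curve, t) / 1000

#' @export
print.AtmosphericC14Curve <- function(x, ...) {
  cat("AtmosphericC14Curve (", x$zone, "): ", length(x$years),
      " points, ", min(x$years), "-", max(x$years), ", peak ",
      format(max(x$delta14c)), " permil\n", sep = "")
  invisible(x)
}

#' Read / write an atmospheric Delta-14C table
#'
#' CSV with columns \code{year}, \code{delta14c} and optionally
#' \code{zone} (Graven-et-al.-style zonal averages).
#'
#' @param path file path.
#' @param curve an \code{AtmosphericC14Curve} to write.
#' @return \code{readAtmC14Curve} returns an
#'   \code{AtmosphericC14Curve}.
#' @export
readAtmC14Curve <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("year", "delta14c"))
    if (!col %in% names(df))
      stop("column '", col, "' missing in ", path, call. = FALSE)
  bad <- which(diff(df$year) <= 0)
  if (length(bad))
    stop("years not strictly increasing at row ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  zone <- if ("zone" %in% names(df)) as.character(df$zone[1]) else "NH"
  atmosphericC14Curve(df$year, df$delta14c, zone)
}

#' @rdname readAtmC14Curve
#' @export
writeAtmC14Curve <- function(curve, path) {
  utils::write.csv(data.frame(year = curve$years,
                              delta14c = curve$delta14c,
                              zone = curve$zone),
                   path, row.names = FALSE)
  invisible(path)
}

#' Synthetic bomb-spike Delta-14C curve
#'
#' Emulates the shape of the observed atmospheric record without any
#' external data: a pre-1950 plateau at 0 per mil (optionally with a
#' small Suess-effect ramp), a rapid rise to the bomb peak in the early
#' 1960s, and an exponential relaxation afterwards.  Deterministic given
#' its parameters.
#'
#' @param from,to span of tabulated years.
#' @param peakYear year of the bomb peak.
#' @param peakValue peak Delta-14C (per mil), > 0.
#' @param riseYears width of the rise from the plateau to the peak.
#' @param declineRate relaxation rate after the peak (1/yr).
#' @param suessSlope plateau slope after 1900 (per mil/yr, <= 0), a
#'   crude fossil-fuel dilution ramp.
#' @return An \code{AtmosphericC14Curve}.
#' @export
syntheticBombCurve <- function(from = 1850, to = 2020, peakYear = 1964,
                               peakValue = 700, riseYears = 9,
                               declineRate = 0.06, suessSlope = -0.3) {
  if (peakValue <= 0) stop("peakValue must be > 0", call. = FALSE)
  years <- seq(from, to, by = 1)
  plateau <- ifelse(years > 1900, suessSlope * (years - 1900), 0)
  rise0 <- peakYear - riseYears
  d14c <- ifelse(years <= rise0, plateau,
          ifelse(years <= peakYear,
                 plateau + (peakValue - plateau) *
                   ((years - rise0) / riseYears)^3,
                 peakValue * exp(-declineRate * (years - peakYear))))
  atmosphericC14Curve(years, d14c, zone = "synthetic")
}

#' Radiocarbon dynamics of a forced compartmental system
#'
#' Propagates the 14C sub-system
#' \deqn{\dot x_{14} = u(t) F_{atm}(t) + (B(t) - \lambda I)\,x_{14}}
#' with \eqn{F_{atm} = 1 + \Delta^{14}C_{atm}/1000}, starting from
#' equilibrium with the curve's earliest value:
#' \eqn{x_{14}(t_s) = -(B - \lambda I)^{-1} u\,F_{atm}(t_s)}.
#' Delta-14C of pool i is \eqn{1000\,(x_{14,i}/x_i - 1)} and of the
#' respiration flux \eqn{1000\,((z^\top x_{14})/(z^\top x) - 1)}.
#' No isotopic fractionation is applied: atmospheric Delta-14C
#' histories are conventionally fractionation-corrected.
#'
#' @param tds a [TimeDependentSystem-class].
#' @param curve an \code{AtmosphericC14Curve}.
#' @param times output years (first element is the spin-up start).
#' @param lambda 14C decay constant (1/yr); default ln(2)/5730.
#' @param rtol,atol solver tolerances.
#' @return A list of class \code{"RadiocarbonRun"}: \code{times},
#'   \code{x14} (matrix, PgC fraction-modern-weighted), \code{x} (bulk
#'   stocks), \code{deltaPools} (matrix, per mil), \code{deltaResp}
#'   (vector, per mil), \code{lambda}.
#' @export
solveRadiocarbon <- function(tds, curve, times,
                             lambda = log(2) / 5730,
                             rtol = 1e-8, atol = 1e-10) {
  n <- nPools(tds@base)
  t1 <- times[1]
  B1 <- tds@BFun(t1); u1 <- tds@uFun(t1)
  x14_0 <- tryCatch(
    solve(-(B1 - lambda * diag(n)), u1 * fractionModern(curve, t1)),
    error = function(e) stop("(B - lambda I) is singular", call. = FALSE))
  rhs <- function(t, y, p) {
    list(as.vector(tds@uFun(t) * fractionModern(curve, t) +
                     (tds@BFun(t) - lambda * diag(n)) %*% y))
  }
  sol <- deSolve::ode(x14_0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  x14 <- sol[, -1, drop = FALSE]
  colnames(x14) <- poolNames(tds@base)
  traj <- solveTrajectory(tds, times, rtol = rtol, atol = atol)
  x <- as.matrix(traj[, poolNames(tds@base), drop = FALSE])
  deltaPools <- 1000 * (x14 / x - 1)
  deltaResp <- vapply(seq_along(times), function(i) {
    z <- -colSums(tds@BFun(times[i]))
    1000 * (sum(z * x14[i, ]) / sum(z * x[i, ]) - 1)
  }, 0)
  structure(list(times = times, x14 = x14, x = x,
                 deltaPools = deltaPools, deltaResp = deltaResp,
                 lambda = lambda, zone = curve$zone),
            class = "RadiocarbonRun")
}

#' @export
print.RadiocarbonRun <- function(x, ...) {
  cat("RadiocarbonRun over", ncol(x$x14), "pools,",
      min(x$times), "-", max(x$times), "\n")
  cat("  respired Delta-14C range:",
      format(range(x$deltaResp), digits = 4), "permil\n")
  invisible(x)
}

#' Scenario-minus-equilibrium respired Delta-14C difference
#'
#' The difference in respired Delta-14C between a forced run and a
#' reference run with the carbon cycle at equilibrium, both driven by
#' the same atmospheric curve on the same time grid.  Positive values
#' indicate a respiration flux with Delta-14C above the equilibrium
#' model's.
#'
#' @param run,reference \code{RadiocarbonRun} objects on identical time
#'   grids.
#' @return data.frame with \code{time} and \code{deltaDiff} (per mil).
#' @export
scenarioDeltaDifference <- function(run, reference) {
  if (length(run$times) != length(reference$times) ||
      any(run$times != reference$times))
    stop("runs must share the time grid", call. = FALSE)
  data.frame(time = run$times,
             deltaDiff = run$deltaResp - reference$deltaResp)
}
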