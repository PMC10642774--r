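#' Twentieth-century global-change forcing functions
#'
#' Idealized trajectories of atmospheric CO2 and global surface
#' temperature for 1850--2020, and the derived scalings of productivity
#' and cycling rates used to force the five-pool terrestrial model.
#'
#' \describe{
#'   \item{\code{co2Curve(t)}}{atmospheric CO2 (ppm): a logistic-type
#'     rise from 285 ppm in 1850, with growth constant 0.0305/yr and
#'     asymptote 2134 ppm.}
#'   \item{\code{temperatureCurve(t)}}{surface temperature (deg C):
#'     15 deg C at 285 ppm with a climate sensitivity of 4.5 deg C per
#'     CO2 doubling.}
#'   \item{\code{co2FertilizationBeta(t)}}{the dimensionless beta factor
#'     of the CO2 fertilization response, built from the photosynthesis
#'     CO2-compensation-style term \code{gammaStar}.}
#'   \item{\code{gppScalingFactor(t)}}{multiplier on the input vector:
#'     \eqn{1 + 2.5\,\beta(t)\ln(x_a(t)/285)}.}
#'   \item{\code{rateModifier(t)}}{dimensionless multiplier on the whole
#'     compartmental matrix: \eqn{\xi = 2^{0.1 T_s - 1.5}}, a Q10-of-2
#'     temperature response equal to 1 at 15 deg C.}
#' }
#'
#' @param t calendar year (vectorized), >= \code{t0}.
#' @param t0 reference year of the pre-industrial state.
#' @param rho dimensionless parameter of the beta factor (default 0.65).
#' @param Tfun temperature trajectory used inside temperature-dependent
#'   terms; pass a frozen function to hold temperature constant.
#' @name forcing
NULL

#' @rdname forcing
#' @export
co2Curve <- function(t, t0 = 1850) {
  e <- exp(0.0305 * (t - t0))
  t0 * e / (t0 + e - 1) + 284
}

#' @rdname forcing
#' @export
temperatureCurve <- function(t, t0 = 1850) {
  15 + 4.5 / log(2) * log(co2Curve(t, t0) / 285)
}

#' @rdname forcing
#' @param Ts surface temperature (deg C).
#' @export
gammaStar <- function(Ts) 42.7 + 1.68 * (Ts - 25) + 0.012 * (Ts - 25)^2

#' @rdname forcing
#' @export
co2FertilizationBeta <- function(t, t0 = 1850, rho = 0.65,
                                 Tfun = function(t) temperatureCurve(t, t0)) {
  xa <- co2Curve(t, t0)
  g <- gammaStar(Tfun(t))
  denom <- (rho * xa - g) * (rho * xa + 2 * g)
  if (any(g <= 0) || any(rho * xa <= g))
    stop("CO2 fertilization forcing outside its validity range ",
         "(rho * xa must exceed gammaStar > 0)", call. = FALSE)
  3 * rho * xa * g / denom
}

#' @rdname forcing
#' @export
gppScalingFactor <- function(t, t0 = 1850, rho = 0.65,
                             Tfun = function(t) temperatureCurve(t, t0)) {
  1 + 2.5 * co2FertilizationBeta(t, t0, rho, Tfun) *
    log(co2Curve(t, t0) / 285)
}

#' @rdname forcing
#' @export
rateModifier <- function(t, t0 = 1850,
                         Tfun = function(t) temperatureCurve(t, t0)) {
  2^(0.1 * Tfun(t) - 1.5)
}

#' Global-change forcing for a compartmental system
#'
#' Builds the time-dependent input vector and compartmental matrix
#' induced by the CO2 and temperature trajectories.  With
#' \code{co2On}, inputs follow \code{gppScalingFactor()} (temperature
#' evolves inside the beta factor, so productivity is identical between
#' the CO2-only and combined runs); with \code{tempOn}, cycling rates
#' follow \code{rateModifier()}.  With both flags off the forcing is the
#' constant base system.
#'
#' @param sys base [CompartmentalSystem-class].
#' @param co2On,tempOn logical scenario flags.
#' @param t0 start year.
#' @param rho beta-factor parameter.
#' @return A [TimeDependentSystem-class] starting from the base steady
#'   state at \code{t0}.
#' @export
globalChangeForcing <- function(sys, co2On = TRUE, tempOn = TRUE,
                                t0 = 1850, rho = 0.65) {
  u0 <- sys@u; B0 <- sys@B
  uFun <- if (co2On) {
    function(t) gppScalingFactor(t, t0, rho) * u0
  } else function(t) u0
  BFun <- if (tempOn) {
    function(t) rateModifier(t, t0) * B0
  } else function(t) B0
  timeDependentSystem(sys, uFun = uFun, BFun = BFun, t0 = t0)
}
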