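#' @import methods
NULL

#' Linear autonomous compartmental system
#'
#' An S4 container for a mass-balanced linear system
#' \deqn{\dot x = u + B x,}
#' where \code{u} is the vector of external carbon inputs (PgC/yr) and
#' \code{B} the compartmental matrix (1/yr).  The compartmental sign
#' structure (non-negative off-diagonals, non-positive diagonals and
#' column sums) guarantees mass balance: the negative of each column sum
#' is the release rate of that pool to the environment.
#'
#' Objects are created with [compartmentalSystem()]; the validity method
#' rejects matrices that fail [validateCompartmental()].
#'
#' @slot u numeric vector of inputs per pool (PgC/yr).
#' @slot B square compartmental matrix (1/yr).
#' @slot poolNames character vector of pool labels.
#' @seealso [steadyState()], [transitTimeDensity()], [emanuelModel()]
#' @export
setClass("CompartmentalSystem",
  representation(u = "numeric", B = "matrix", poolNames = "character"))

setValidity("CompartmentalSystem", function(object) {
  rep <- validateCompartmental(object@B)
  msgs <- rep$violations
  if (length(object@u) != nrow(object@B))
    msgs <- c(msgs, "length(u) must equal nrow(B)")
  if (any(object@u < 0))
    msgs <- c(msgs, "all entries of u must be >= 0")
  if (sum(object@u) <= 0)
    msgs <- c(msgs, "at least one entry of u must be > 0")
  if (length(object@poolNames) != nrow(object@B))
    msgs <- c(msgs, "poolNames must have one label per pool")
  if (length(msgs)) msgs else TRUE
})

#' Non-autonomous linear compartmental system
#'
#' Wraps a base [CompartmentalSystem-class] (the pre-perturbation
#' equilibrium system) together with time-dependent forcing
#' \eqn{u(t)} and \eqn{B(t)}, a start time \code{t0} and initial stocks
#' \code{x0} (defaulting to the base steady state).  The forced system is
#' \deqn{\dot y = B(t) y + u(t), \quad y(t_0) = x_0.}
#'
#' @slot base the autonomous system before perturbation.
#' @slot uFun function of time returning the input vector (PgC/yr).
#' @slot BFun function of time returning the compartmental matrix (1/yr).
#' @slot t0 start time (calendar yr).
#' @slot x0 initial stocks (PgC).
#' @seealso [timeDependentSystem()], [bttDistribution()],
#'   [solveTrajectory()]
#' @export
setClass("TimeDependentSystem",
  representation(base = "CompartmentalSystem", uFun = "function",
                 BFun = "function", t0 = "numeric", x0 = "numeric"))

setValidity("TimeDependentSystem", function(object) {
  msgs <- character()
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msgs <- c(msgs, "t0 must be a single finite number")
  if (length(object@x0) != nPools(object@base))
    msgs <- c(msgs, "x0 must have one entry per pool")
  if (any(object@x0 < 0))
    msgs <- c(msgs, "initial stocks must be >= 0")
  if (length(msgs)) msgs else TRUE
})
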