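## Matrix exponential and grid propagation helpers -------------------------

expMat <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

## e^{a_i B} v for all ages on a grid.  Uniform stretches are advanced by
## repeated application of one cached step exponential; the accumulated
## product is checked against a direct evaluation every `checkEvery`
## steps to bound drift.
propagateAges <- function(B, v, ages, checkEvery = 50L, checkTol = 1e-9) {
  n <- length(v)
  out <- matrix(NA_real_, n, length(ages))
  cache <- list()
  cur <- v; curAge <- 0; sinceCheck <- 0L
  for (i in seq_along(ages)) {
    da <- ages[i] - curAge
    if (da > 0) {
      key <- sprintf("%.12g", da)
      if (is.null(cache[[key]])) cache[[key]] <- expMat(da * B)
      cur <- cache[[key]] %*% cur
      curAge <- ages[i]
      sinceCheck <- sinceCheck + 1L
      if (sinceCheck >= checkEvery) {
        direct <- expMat(curAge * B) %*% v
        drift <- max(abs(cur - direct)) / max(1, max(abs(direct)))
        if (drift > checkTol) cur <- direct
        sinceCheck <- 0L
      }
    }
    out[, i] <- cur
  }
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

## Survival of the equilibrium transit time, 1 - CDF
ttSurvival <- function(sys, tau) {
  sapply(tau, function(a) sum(expMat(a * sys@B) %*% sys@u) / sum(sys@u))
}

#' Default age grid for a system
#'
#' Ages are finely spaced up to 5 yr (where the density's curvature
#' concentrates and the equilibrium median of a few years must be
#' resolved), with the spacing shrunk in proportion to the fastest pool
#' rate so trapezoidal quadrature error stays below the tail tolerance;
#' then 0.1 yr up to \code{fineMax}, then geometric coarsening until the
#' truncated transit-time mass beyond the grid is below
#' \code{tail_tol}.
#'
#' @param sys a [CompartmentalSystem-class]; sets the near-zero
#'   resolution and how far the tail must extend.
#' @param tail_tol maximum probability mass allowed beyond the grid.
#' @param fineMax end of the uniformly spaced region (yr).
#' @param by spacing on (5, fineMax] (yr); the spacing on [0, 5] is
#'   \code{by/5} divided by the fastest pool rate when that exceeds 1.
#' @param growth geometric coarsening factor beyond \code{fineMax}.
#' @return numeric vector of ages (yr), starting at 0.
#' @export
makeAgeGrid <- function(sys, tail_tol = 1e-4, fineMax = 100, by = 0.1,
                        growth = 1.05) {
  h0 <- (by / 5) / max(1, max(-diag(sys@B)))
  fine <- c(seq(0, 5, by = h0), seq(5 + by, fineMax, by = by))
  if (ttSurvival(sys, fineMax) <= tail_tol) return(fine)
  coarse <- numeric(); a <- fineMax
  repeat {
    a <- a * growth
    coarse <- c(coarse, a)
    if (ttSurvival(sys, a) <= tail_tol || a > 1e5) break
  }
  c(fine, coarse)
}

densityOnAgeGrid <- function(ages, values, kind, poolNames = NULL) {
  structure(list(ages = ages, values = values, kind = kind,
                 poolNames = poolNames),
            class = "DensityOnAgeGrid")
}

#' @export
print.DensityOnAgeGrid <- function(x, ...) {
  cat("DensityOnAgeGrid (", x$kind, "): ", length(x$ages),
      " ages in [0, ", format(max(x$ages)), "] yr\n", sep = "")
  invisible(x)
}

## Distributions at equilibrium --------------------------------------------

#' Per-pool age density at equilibrium
#'
#' The age density of carbon in each pool of a system at steady state,
#' \eqn{(X^*)^{-1} e^{aB} u}, evaluated on an age grid.  Each pool's
#' component is a proper probability density integrating to one.
#'
#' @param sys a [CompartmentalSystem-class].
#' @param steady its steady state from [steadyState()]; recomputed when
#'   missing.
#' @param ages age grid (yr); defaults to [makeAgeGrid()].
#' @return A \code{DensityOnAgeGrid} whose \code{values} is a matrix with
#'   one row per pool (1/yr).
#' @export
poolAgeDensity <- function(sys, steady = steadyState(sys),
                           ages = makeAgeGrid(sys)) {
  if (any(steady$x_star <= 0))
    stop("pool age density undefined for pools with zero stock",
         call. = FALSE)
  m <- propagateAges(sys@B, sys@u, ages)       # e^{aB} u
  vals <- m / steady$x_star                    # (X*)^-1 e^{aB} u, rowwise
  rownames(vals) <- sys@poolNames
  densityOnAgeGrid(ages, vals, "pool_age_pdf", sys@poolNames)
}

#' System-age density at equilibrium
#'
#' The age density of all carbon stored in the system at steady state,
#' \eqn{f_A(a) = -\mathbf{1}^\top B e^{aB} x^* / \|x^*\|}.
#'
#' @inheritParams poolAgeDensity
#' @return A scalar-valued \code{DensityOnAgeGrid} (1/yr).
#' @export
systemAgeDensity <- function(sys, steady = steadyState(sys),
                             ages = makeAgeGrid(sys)) {
  m <- propagateAges(sys@B, steady$x_star, ages)
  vals <- as.numeric(-colSums(sys@B %*% m)) / steady$total_stock
  densityOnAgeGrid(ages, pmax(vals, 0), "system_age_pdf")
}

#' Transit-time density at equilibrium
#'
#' The density of the time carbon spends between uptake and release,
#' \eqn{f_T(\tau) = -\mathbf{1}^\top B e^{\tau B} u / \|u\|}, the
#' phase-type density of the absorbing Markov chain defined by B.  The
#' per-pool decomposition attributes the density to the pool from which
#' carbon is released: component j is the release rate of pool j times
#' \eqn{(e^{\tau B} u)_j / \|u\|}; the components sum to \eqn{f_T}.
#'
#' @inheritParams poolAgeDensity
#' @return A \code{DensityOnAgeGrid} with scalar \code{values} (1/yr) and
#'   an element \code{byPool}: the per-pool decomposition matrix.
#' @examples
#' ft <- transitTimeDensity(emanuelModel())
#' ft$values[1]   # density at age 0
#' @export
transitTimeDensity <- function(sys, ages = makeAgeGrid(sys)) {
  U <- sum(sys@u)
  if (U <= 0) stop("total input is zero; transit time undefined",
                   call. = FALSE)
  m <- propagateAges(sys@B, sys@u, ages)       # e^{tau B} u
  byPool <- (releaseRates(sys) * m) / U
  rownames(byPool) <- sys@poolNames
  vals <- pmax(colSums(byPool), 0)
  out <- densityOnAgeGrid(ages, vals, "transit_time_pdf")
  out$byPool <- byPool
  out
}

#' Moments of the equilibrium transit-time distribution
#'
#' Closed forms: mean \eqn{\mathbf{1}^\top(-B^{-1})u/\|u\| =
#' \|x^*\|/\|u\|}, second moment \eqn{2\,\mathbf{1}^\top B^{-2} u/\|u\|}.
#'
#' @param sys a [CompartmentalSystem-class].
#' @return A list with \code{mean} and \code{sd} (yr).
#' @examples
#' transitTimeMoments(emanuelModel())  # mean 15.58, sd 45.0 yr
#' @export
transitTimeMoments <- function(sys) {
  rep <- validateCompartmental(sys@B)
  if (!rep$invertible)
    stop("compartmental matrix is singular; moments undefined",
         call. = FALSE)
  U <- sum(sys@u)
  m1 <- sum(solve(-sys@B, sys@u)) / U
  m2 <- 2 * sum(solve(sys@B %*% sys@B, sys@u)) / U
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Quantiles of the equilibrium transit-time distribution
#'
#' Solves \eqn{1 - \mathbf{1}^\top e^{\tau B} u/\|u\| = \alpha} for
#' \eqn{\tau} by bracketed root-finding on the closed-form CDF.
#'
#' @param sys a [CompartmentalSystem-class].
#' @param alpha probabilities in (0, 1); vectorized.
#' @param tol absolute root tolerance (yr).
#' @return Ages (yr), one per \code{alpha}.
#' @examples
#' transitTimeQuantile(emanuelModel(), 0.5)  # median, 2.29 yr
#' @export
transitTimeQuantile <- function(sys, alpha, tol = 1e-8) {
  if (any(alpha <= 0 | alpha >= 1))
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  sapply(alpha, function(p) {
    hi <- 1
    while (1 - ttSurvival(sys, hi) < p && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(a) 1 - ttSurvival(sys, a) - p,
                   lower = 0, upper = hi, tol = tol)$root
  })
}
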