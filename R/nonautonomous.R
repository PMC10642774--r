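#' Construct a non-autonomous compartmental system
#'
#' @param base a [CompartmentalSystem-class]: the pre-perturbation
#'   equilibrium system.
#' @param uFun function of time returning the input vector (PgC/yr);
#'   defaults to the constant base input.
#' @param BFun function of time returning the compartmental matrix
#'   (1/yr); defaults to the constant base matrix.
#' @param t0 start time (calendar yr).
#' @param x0 initial stocks (PgC); defaults to the base steady state, the
#'   assumption under which the equilibrium-age carry-over of
#'   [ageMassDensity()] holds.
#' @return A [TimeDependentSystem-class].
#' @export
timeDependentSystem <- function(base, uFun = NULL, BFun = NULL, t0 = 0,
                                x0 = NULL) {
  u0 <- base@u; B0 <- base@B
  if (is.null(uFun)) uFun <- function(t) u0
  if (is.null(BFun)) BFun <- function(t) B0
  if (is.null(x0)) x0 <- steadyState(base)$x_star
  new("TimeDependentSystem", base = base, uFun = uFun, BFun = BFun,
      t0 = t0, x0 = as.numeric(x0))
}

setMethod("show", "TimeDependentSystem", function(object) {
  cat("TimeDependentSystem over", nPools(object@base), "pools, t0 =",
      object@t0, "\n")
  cat("  initial stock:", format(sum(object@x0)), "PgC\n")
  invisible(object)
})

#' Solve pool trajectories of a forced compartmental system
#'
#' Integrates \eqn{\dot y = B(t) y + u(t)} from \code{t0} with a
#' stiff-capable solver.  Two auxiliary states accumulate total input and
#' total release, so mass balance
#' \eqn{\|x(t)\| - \|x_0\| = \int (\|u\| - R_e)\,dt} can be checked to
#' solver accuracy.
#'
#' @param tds a [TimeDependentSystem-class].
#' @param times output times (yr), starting at or after \code{t0}.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns \code{time}, one per pool (PgC),
#'   \code{cumInput} and \code{cumRelease} (PgC since \code{t0}).
#' @export
solveTrajectory <- function(tds, times, rtol = 1e-8, atol = 1e-10) {
  if (any(times < tds@t0)) stop("times must be >= t0", call. = FALSE)
  n <- nPools(tds@base)
  rhs <- function(t, y, p) {
    x <- y[seq_len(n)]
    Bt <- tds@BFun(t); ut <- tds@uFun(t)
    dx <- Bt %*% x + ut
    list(c(dx, sum(ut), sum(-colSums(Bt) * x)))
  }
  tt <- unique(c(tds@t0, times))
  sol <- deSolve::ode(c(tds@x0, 0, 0), tt, rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("trajectory solver failed to converge; see deSolve diagnostics",
         call. = FALSE)
  out <- as.data.frame(sol[match(times, tt), , drop = FALSE])
  names(out) <- c("time", poolNames(tds@base), "cumInput", "cumRelease")
  out
}

#' State-transition operator of a forced compartmental system
#'
#' Solves \eqn{d\Phi/dt = B(t)\,\Phi} with \eqn{\Phi(s, s) = I}, the
#' operator propagating pool contents from time \code{s} to \code{t}.
#'
#' @param tds a [TimeDependentSystem-class].
#' @param s,t times with \code{t0 <= s <= t}.
#' @param rtol,atol solver tolerances.
#' @return The n-by-n matrix \eqn{\Phi(t, s)}.
#' @export
stateTransition <- function(tds, s, t, rtol = 1e-10, atol = 1e-12) {
  if (s < tds@t0) stop("s must be >= t0", call. = FALSE)
  if (s > t) stop("backward evaluation (s > t) is not supported",
                  call. = FALSE)
  n <- nPools(tds@base)
  if (s == t) return(diag(n))
  rhs <- function(tt, y, p) list(as.vector(tds@BFun(tt) %*% matrix(y, n, n)))
  sol <- deSolve::ode(as.vector(diag(n)), c(s, t), rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  matrix(sol[nrow(sol), -1], n, n)
}

#' Annual cache of the state-transition operator
#'
#' Stores \eqn{\Phi(t_k, t_0)} on a grid, built sequentially via the
#' cocycle property; off-grid times are reached by solving the short ODE
#' from the nearest cached node below (no matrix interpolation, which
#' could violate positivity).
#'
#' @param tds a [TimeDependentSystem-class].
#' @param times grid of cache times starting at \code{t0}.
#' @return A list of class \code{"StateTransitionCache"}.
#' @export
stateTransitionCache <- function(tds, times) {
  times <- sort(unique(c(tds@t0, times)))
  n <- nPools(tds@base)
  phis <- vector("list", length(times))
  phis[[1]] <- diag(n)
  for (k in seq_along(times)[-1])
    phis[[k]] <- stateTransition(tds, times[k - 1], times[k]) %*%
      phis[[k - 1]]
  structure(list(times = times, phis = phis, tds = tds),
            class = "StateTransitionCache")
}

#' @rdname stateTransitionCache
#' @param cache a \code{StateTransitionCache}.
#' @param t evaluation time; returns \eqn{\Phi(t, t_0)}.
#' @export
phiAt <- function(cache, t) {
  if (t < cache$times[1]) stop("t before cache start", call. = FALSE)
  k <- findInterval(t, cache$times)
  phi <- cache$phis[[k]]
  if (t > cache$times[k])
    phi <- stateTransition(cache$tds, cache$times[k], t) %*% phi
  phi
}

## psi(a) = Phi(t, t - a) for fixed evaluation time t, integrated in the
## age variable: d psi/da = psi B(t - a), psi(0) = I.  This is the stable
## route to ages spanning a century or more, where composing cached Phi
## factors would require inverting matrices with entries below 1e-300.
## Two auxiliary blocks integrate X(a) = int_0^a psi u(t-a') da' and its
## age-weighted counterpart, so in-window stocks and age moments are
## exact to solver accuracy instead of quadrature accuracy.
psiAges <- function(tds, t, ages, rtol = 1e-8, atol = 1e-10) {
  n <- nPools(tds@base)
  if (length(ages) == 1L && ages == 0)
    return(list(psi = array(diag(n), c(n, n, 1L)),
                stockIn = numeric(n), ageStockIn = numeric(n)))
  rhs <- function(a, y, p) {
    psi <- matrix(y[seq_len(n * n)], n, n)
    mu <- psi %*% tds@uFun(t - a)
    list(c(as.vector(psi %*% tds@BFun(t - a)), mu, a * mu))
  }
  y0 <- c(as.vector(diag(n)), numeric(2 * n))
  sol <- deSolve::ode(y0, ages, rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("state-transition solver failed over the age range",
         call. = FALSE)
  last <- sol[nrow(sol), -1]
  list(psi = array(t(sol[, 1 + seq_len(n * n), drop = FALSE]),
                   c(n, n, length(ages))),
       stockIn = last[n * n + seq_len(n)],
       ageStockIn = last[n * n + n + seq_len(n)])
}

#' Age-resolved mass density of a forced system
#'
#' Mass in the system at time \code{t} with age \code{a}, per pool:
#' \eqn{m(t,a) = \Phi(t, t-a)\,u(t-a)} for ages younger than the run
#' (\eqn{a < t - t_0}), and the equilibrium-age carry-over
#' \eqn{\Phi(t, t_0)\, e^{(a - (t - t_0))B} u} for older carbon that was
#' already in the system at \code{t0}.  Its integral over age equals the
#' stock vector \eqn{x(t)} componentwise.
#'
#' @param tds a [TimeDependentSystem-class] initialized at the base
#'   steady state.
#' @param t evaluation time (>= t0).
#' @param ages age grid (yr); defaults to [makeAgeGrid()] of the base
#'   system.
#' @return A \code{DensityOnAgeGrid} (kind \code{age_mass_density}, PgC
#'   per yr of age) with one row per pool, plus elements
#'   \code{tailStock} and \code{tailAgeStock}: the per-pool mass and
#'   age-weighted mass beyond the last grid age, from the analytic
#'   equilibrium tail.
#' @export
ageMassDensity <- function(tds, t, ages = makeAgeGrid(tds@base)) {
  pieces <- bttPieces(tds, t, ages)
  out <- densityOnAgeGrid(ages, pieces$m, "age_mass_density",
                          poolNames(tds@base))
  out$stockIn <- pieces$stockIn
  out$ageStockIn <- pieces$ageStockIn
  out$tailStock <- pieces$tailStock
  out$tailAgeStock <- pieces$tailAgeStock
  out$time <- t
  out
}

## Shared evaluation of m(t, a) and the respiration-age density r(t, a)
## on an age grid, with the analytic equilibrium tail beyond the grid.
bttPieces <- function(tds, t, ages, rtol = 1e-8, atol = 1e-10) {
  if (t < tds@t0) stop("t must be >= t0", call. = FALSE)
  base <- tds@base; B <- base@B; u <- base@u; n <- nPools(base)
  D <- t - tds@t0
  inWin <- ages[ages < D]
  aPsi <- unique(c(inWin, D))
  ps <- psiAges(tds, t, aPsi, rtol = rtol, atol = atol)
  psi <- ps$psi
  psiD <- psi[, , length(aPsi)]
  m <- matrix(NA_real_, n, length(ages))
  iIn <- which(ages < D)
  for (j in seq_along(iIn))
    m[, iIn[j]] <- psi[, , j] %*% tds@uFun(t - ages[iIn[j]])
  iOut <- which(ages >= D)
  if (length(iOut)) {
    eq <- propagateAges(B, u, ages[iOut] - D)   # e^{(a-D)B} u
    m[, iOut] <- psiD %*% eq
  }
  zt <- -colSums(tds@BFun(t))                   # release rates at t
  r <- as.numeric(zt %*% m)
  nBi <- solve(-B)
  ## carry-over mass beyond D, m(a) = psiD e^{(a-D)B} u, integrated
  ## analytically from the last grid age amax (or from D when the grid
  ## ends inside the run window)
  amax <- max(ages[length(ages)], D)
  w <- expMat((amax - D) * B) %*% u
  tailStock <- as.numeric(psiD %*% nBi %*% w)
  tailAgeStock <- as.numeric(psiD %*% (amax * nBi + nBi %*% nBi) %*% w)
  ## exact per-pool stock and age moment of the D-to-amax carry-over
  w0 <- nBi %*% u - nBi %*% w                      # int_0^{amax-D} e^{sB}u ds
  w1 <- nBi %*% nBi %*% u -
    (nBi %*% nBi + (amax - D) * nBi) %*% w         # int s e^{sB}u ds
  carryStock <- as.numeric(psiD %*% w0)
  carryAgeStock <- as.numeric(psiD %*% (D * w0 + w1))
  stockIn <- ps$stockIn + carryStock               # exact int_0^{amax} m da
  ageStockIn <- ps$ageStockIn + carryAgeStock
  names(tailStock) <- names(tailAgeStock) <- poolNames(base)
  names(stockIn) <- names(ageStockIn) <- poolNames(base)
  list(ages = ages, m = m, r = r, zt = zt, psiD = psiD,
       stockIn = stockIn, ageStockIn = ageStockIn,
       tailStock = tailStock, tailAgeStock = tailAgeStock,
       D = D, base = base)
}

## Summaries from a gridded respiration-age density.  Total mass and
## mean come from the exact (solver-integrated plus analytic-tail)
## moments; quantiles use linear interpolation of the trapezoidal CDF.
bttSummarize <- function(ages, r, total, meanAge,
                         alphas = c(0.05, 0.5, 0.95)) {
  if (total <= 0) stop("total respiration is zero", call. = FALSE)
  dcdf <- c(0, cumsum(diff(ages) * (utils::head(r, -1) +
                                    utils::tail(r, -1)) / 2))
  qs <- sapply(alphas, function(p) {
    target <- p * total
    if (target > dcdf[length(dcdf)]) return(NA_real_)  # inside tail mass
    stats::approx(dcdf, ages, xout = target, ties = "ordered")$y
  })
  names(qs) <- paste0("q", formatC(100 * alphas, width = 2, flag = "0"))
  list(total = total, mean = meanAge, quantiles = qs,
       median = unname(qs[which(abs(alphas - 0.5) < 1e-12)[1]]))
}

#' Backward transit-time distribution of a forced system
#'
#' The age distribution of carbon in the respiration flux at time
#' \code{t}: the respiration-age density \eqn{r(t,a) = z^\top(t)\,
#' m(t,a)} with \eqn{z^\top(t) = -\mathbf{1}^\top B(t)} the release-rate
#' vector, normalized by the total respiration \eqn{R_e(t) = \int r\,
#' da}.  Mass beyond the last grid age is carried analytically from the
#' equilibrium tail, so the mean is exact to solver accuracy and not
#' truncated at the grid.
#'
#' @param tds a [TimeDependentSystem-class] initialized at the base
#'   steady state.
#' @param t evaluation time.
#' @param ages age grid (yr).
#' @param alphas quantile probabilities to report (median included).
#' @param keepMass keep the per-pool mass density (needed for
#'   [meanSystemAge()] and conservation checks).
#' @return An object of class \code{"BTTDistribution"}: list with
#'   \code{time}, \code{ages}, \code{density} (PgC/yr per yr of age),
#'   \code{totalRespiration} (PgC/yr), \code{pdf}, \code{mean},
#'   \code{median}, \code{quantiles}, tail scalars and (optionally)
#'   \code{massDensity}.
#' @export
bttDistribution <- function(tds, t, ages = makeAgeGrid(tds@base),
                            alphas = c(0.05, 0.5, 0.95),
                            keepMass = TRUE) {
  alphas <- sort(unique(c(alphas, 0.5)))
  p <- bttPieces(tds, t, ages)
  tailMass <- sum(p$zt * p$tailStock)
  tailAgeMoment <- sum(p$zt * p$tailAgeStock)
  total <- sum(p$zt * p$stockIn) + tailMass
  meanAge <- (sum(p$zt * p$ageStockIn) + tailAgeMoment) / total
  s <- bttSummarize(ages, p$r, total, meanAge, alphas)
  out <- structure(list(
    time = t, ages = ages, density = p$r,
    totalRespiration = s$total, pdf = p$r / s$total,
    mean = s$mean, median = s$median, quantiles = s$quantiles,
    tailMass = tailMass, tailAgeMoment = tailAgeMoment),
    class = "BTTDistribution")
  if (keepMass) {
    out$massDensity <- p$m
    out$stockIn <- p$stockIn
    out$ageStockIn <- p$ageStockIn
    out$tailStock <- p$tailStock
    out$tailAgeStock <- p$tailAgeStock
  }
  out
}

#' @export
print.BTTDistribution <- function(x, ...) {
  cat("Backward transit-time distribution at t =", x$time, "\n")
  cat("  total respiration:", format(x$totalRespiration), "PgC/yr\n")
  cat("  mean:", format(x$mean), "yr; median:", format(x$median), "yr\n")
  invisible(x)
}

#' Equilibrium backward transit-time distribution
#'
#' The autonomous special case of [bttDistribution()]: the
#' respiration-age density \eqn{r(a) = z^\top e^{aB} u} of a system at
#' steady state, whose pdf is the closed-form transit-time density.
#'
#' @inheritParams bttDistribution
#' @param sys a [CompartmentalSystem-class].
#' @export
equilibriumBTT <- function(sys, ages = makeAgeGrid(sys),
                           alphas = c(0.05, 0.5, 0.95), keepMass = TRUE) {
  bttDistribution(timeDependentSystem(sys, t0 = 0), 0, ages = ages,
                  alphas = alphas, keepMass = keepMass)
}

#' Mean system age of a forced system
#'
#' \eqn{E_A(t) = \int a\,\mathbf{1}^\top m(t,a)\,da \;/\; \|x(t)\|},
#' with the stock taken from the age-mass density itself (conservation
#' makes it agree with the trajectory solution).
#'
#' @inheritParams bttDistribution
#' @return Mean age (yr).
#' @export
meanSystemAge <- function(tds, t, ages = makeAgeGrid(tds@base)) {
  p <- bttPieces(tds, t, ages)
  stock <- sum(p$stockIn) + sum(p$tailStock)
  if (stock <= 0) stop("total stock is zero", call. = FALSE)
  (sum(p$ageStockIn) + sum(p$tailAgeStock)) / stock
}

#' Time series of backward transit-time summaries
#'
#' Evaluates [bttDistribution()] at each requested time and assembles
#' mean, median and quantiles of the BTT together with GPP
#' (\eqn{\|u(t)\|}), ecosystem respiration \eqn{R_e(t)}, total stock,
#' mean system age and the homogeneity ratios.
#'
#' @inheritParams bttDistribution
#' @param times evaluation times.
#' @return A data.frame with one row per time: \code{time, GPP, Re, Eb,
#'   mb, q05, q95, totalStock, EA, h, hPrime}.
#' @export
bttSummarySeries <- function(tds, times, ages = makeAgeGrid(tds@base),
                             alphas = c(0.05, 0.5, 0.95)) {
  traj <- solveTrajectory(tds, times)
  stocks <- as.matrix(traj[, poolNames(tds@base), drop = FALSE])
  rows <- lapply(seq_along(times), function(i) {
    t <- times[i]
    p <- bttPieces(tds, t, ages)
    total <- sum(p$zt * p$stockIn) + sum(p$zt * p$tailStock)
    meanAge <- (sum(p$zt * p$ageStockIn) + sum(p$zt * p$tailAgeStock)) /
      total
    s <- bttSummarize(ages, p$r, total, meanAge, alphas)
    stock <- sum(p$stockIn) + sum(p$tailStock)
    EA <- (sum(p$ageStockIn) + sum(p$tailAgeStock)) / stock
    data.frame(time = t, GPP = sum(tds@uFun(t)),
               Re = s$total, Eb = s$mean, mb = s$median,
               q05 = unname(s$quantiles["q05"]),
               q95 = unname(s$quantiles["q95"]),
               totalStock = sum(stocks[i, ]), EA = EA,
               h = homogeneityH(s$median, s$mean),
               hPrime = homogeneityHPrime(s$mean, EA))
  })
  do.call(rbind, rows)
}
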