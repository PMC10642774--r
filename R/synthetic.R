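## Synthetic systems and the Monte-Carlo particle oracle.  The oracle
## simulates individual carbon atoms through the continuous-time Markov
## chain defined by the columns of B and is kept fully independent of the
## matrix-exponential machinery it validates.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random valid compartmental system
#'
#' Draws a compartmental matrix with log-normally distributed per-pool
#' turnover rates, random internal transfers, and a strictly positive
#' release fraction in every pool (so every generated matrix passes
#' [validateCompartmental()] and is invertible); inputs are non-negative
#' with a guaranteed positive entry.  Deterministic given \code{seed}.
#'
#' @param n number of pools (>= 1).
#' @param connectivity probability of each off-diagonal transfer.
#' @param rateScale median turnover rate (1/yr).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param maxTries retries before giving up on an invertible draw.
#' @return A [CompartmentalSystem-class].
#' @export
randomSystem <- function(n, connectivity = 0.5, rateScale = 1,
                         seed = NULL, maxTries = 100L) {
  stopifnot(n >= 1)
  withSeed(seed, {
    for (try in seq_len(maxTries)) {
      k <- rateScale * exp(stats::rnorm(n, 0, 1))   # turnover rates
      B <- matrix(0, n, n)
      for (i in seq_len(n)) {
        rel <- stats::runif(1, 0.1, 1)              # release fraction
        to <- setdiff(seq_len(n), i)
        to <- to[stats::runif(length(to)) < connectivity]
        w <- if (length(to)) stats::runif(length(to)) else numeric()
        if (length(to)) B[to, i] <- (1 - rel) * k[i] * w / sum(w)
        B[i, i] <- -k[i]
      }
      u <- ifelse(stats::runif(n) < 0.7, stats::runif(n, 0.1, 10), 0)
      if (all(u == 0)) u[1] <- 1
      rep <- validateCompartmental(B)
      if (rep$valid)
        return(compartmentalSystem(u, B))
    }
    stop("failed to draw an invertible compartmental matrix in ",
         maxTries, " tries", call. = FALSE)
  })
}

## cumulative destination probabilities per source pool: rows 1..n are
## transfers, row n+1 is release to the environment
destCumProbs <- function(B) {
  n <- nrow(B)
  q <- -diag(B)
  P <- rbind(B, -colSums(B))
  diag(P) <- 0
  apply(sweep(P, 2, q, "/"), 2, cumsum)
}

#' Monte-Carlo particle oracle for equilibrium transit times
#'
#' Simulates individual carbon atoms through the absorbing Markov chain
#' of an autonomous system at steady state: entry pool drawn
#' proportional to u, exponential sojourns with the per-pool total rates
#' \eqn{-B_{ii}}, jumps and release drawn from the columns of B.  The
#' exit ages are draws from the phase-type transit-time distribution and
#' serve as an independent check on the closed-form machinery.
#'
#' @param sys a [CompartmentalSystem-class].
#' @param nParticles number of atoms.
#' @param seed integer seed for reproducibility.
#' @param maxJumps safety bound on jumps per atom.
#' @return A data.frame of class \code{"ParticleEnsemble"} with columns
#'   \code{entry_time}, \code{exit_time}, \code{exit_age} (yr),
#'   \code{entry_pool}, \code{exit_pool}.
#' @examples
#' mean(particleOracle(compartmentalSystem(1, matrix(-1)), 1e4,
#'                     seed = 1)$exit_age)  # ~1
#' @export
particleOracle <- function(sys, nParticles, seed = NULL,
                           maxJumps = 1e5L) {
  n <- nPools(sys)
  q <- -diag(sys@B)
  cum <- destCumProbs(sys@B)
  withSeed(seed, {
    state <- sample.int(n, nParticles, replace = TRUE,
                        prob = sys@u / sum(sys@u))
    entry <- state
    age <- numeric(nParticles)
    exitPool <- integer(nParticles)
    alive <- rep(TRUE, nParticles)
    jumps <- 0L
    while (any(alive)) {
      jumps <- jumps + 1L
      if (jumps > maxJumps) stop("particle exceeded maxJumps jumps",
                                 call. = FALSE)
      i <- which(alive)
      s <- state[i]
      age[i] <- age[i] + stats::rexp(length(i), q[s])
      r <- stats::runif(length(i))
      dest <- 1L + colSums(cum[, s, drop = FALSE] <
                             matrix(r, n + 1L, length(i), byrow = TRUE))
      out <- dest > n
      exitPool[i[out]] <- s[out]
      alive[i[out]] <- FALSE
      state[i[!out]] <- dest[!out]
    }
    structure(data.frame(entry_time = 0, exit_time = age,
                         exit_age = age, entry_pool = entry,
                         exit_pool = exitPool),
              class = c("ParticleEnsemble", "data.frame"))
  })
}

#' Monte-Carlo particle oracle for forced systems
#'
#' Time-inhomogeneous version of [particleOracle()]: entry times follow
#' an inhomogeneous Poisson process with rate \eqn{\|u(t)\|} (sampled by
#' inverse transform on a fine grid), entry pools follow
#' \eqn{u(t)/\|u(t)\|}, and within-system jumps are drawn from the
#' time-varying chain by thinning against per-pool rate upper bounds
#' recomputed on a fine grid.  Carbon already stored at \code{t0} is
#' represented by extending the entry process \code{burnIn} years into
#' the pre-perturbation past, where the system is the constant base
#' system at equilibrium; \code{burnIn} defaults to an age beyond which
#' the base system retains less than 2e-4 of entering mass.  Atoms still
#' inside after \code{window[2]} are discarded (they cannot exit in the
#' window), so the exit ages of atoms released inside \code{window} are
#' an empirical draw of the backward transit time over that window.
#'
#' @param tds a [TimeDependentSystem-class].
#' @param nParticles number of atoms to enter during
#'   \code{[t0 - burnIn, window[2]]}.
#' @param window exit-observation window \code{c(from, to)}.
#' @param seed integer seed.
#' @param gridBy spacing of the entry-sampling and rate-bound grids
#'   (yr).
#' @param burnIn length of the pre-t0 equilibrium entry period (yr).
#' @return A \code{ParticleEnsemble} restricted to atoms exiting inside
#'   the window.
#' @export
particleOracleTD <- function(tds, nParticles, window, seed = NULL,
                             gridBy = 0.25, burnIn = NULL) {
  n <- nPools(tds@base)
  t0 <- tds@t0; tEnd <- window[2]
  if (tEnd <= t0) stop("window must end after t0", call. = FALSE)
  if (is.null(burnIn)) {
    burnIn <- 10
    while (ttSurvival(tds@base, burnIn) > 2e-4 && burnIn < 1e5)
      burnIn <- burnIn * 2
  }
  ## before t0 the system is the constant base system at equilibrium
  baseB <- tds@base@B; baseU <- tds@base@u
  Bf <- function(t) if (t < t0) baseB else tds@BFun(t)
  uf <- function(t) if (t < t0) baseU else tds@uFun(t)
  tg <- seq(t0 - burnIn, tEnd, by = gridBy)
  qg <- vapply(tg, function(t) -diag(Bf(t)), numeric(n))
  Q <- apply(qg, 1, max) * 1.0001               # per-pool bounds
  withSeed(seed, {
    ## entry times: inverse transform on the cumulative input rate
    rate <- vapply(tg, function(t) sum(uf(t)), 0)
    cumIn <- c(0, cumsum((utils::head(rate, -1) + utils::tail(rate, -1)) / 2 *
                           diff(tg)))
    entryT <- stats::approx(cumIn / cumIn[length(cumIn)], tg,
                            xout = stats::runif(nParticles))$y
    entryP <- vapply(entryT, function(te) {
      ut <- uf(te)
      sample.int(n, 1L, prob = ut / sum(ut))
    }, 0L)
    tCur <- entryT; state <- entryP
    exitT <- rep(NA_real_, nParticles)
    exitP <- integer(nParticles)
    alive <- rep(TRUE, nParticles)
    while (any(alive)) {
      i <- which(alive)
      tCur[i] <- tCur[i] + stats::rexp(length(i), Q[state[i]])
      gone <- tCur[i] > tEnd
      alive[i[gone]] <- FALSE                    # cannot exit in window
      i <- i[!gone]
      if (!length(i)) next
      for (p in i) {                             # thinning + destination
        Bt <- Bf(tCur[p])
        s <- state[p]
        qs <- -Bt[s, s]
        if (stats::runif(1) < qs / Q[s]) {
          probs <- c(Bt[, s], -sum(Bt[, s]))
          probs[s] <- 0
          dest <- sample.int(n + 1L, 1L, prob = probs)
          if (dest > n) {
            exitT[p] <- tCur[p]; exitP[p] <- s; alive[p] <- FALSE
          } else state[p] <- dest
        }
      }
    }
    keep <- !is.na(exitT) & exitT >= window[1] & exitT <= window[2]
    structure(data.frame(entry_time = entryT[keep],
                         exit_time = exitT[keep],
                         exit_age = exitT[keep] - entryT[keep],
                         entry_pool = entryP[keep],
                         exit_pool = exitP[keep]),
              class = c("ParticleEnsemble", "data.frame"))
  })
}
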