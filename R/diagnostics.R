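#' Homogeneity ratios of the transit-time distribution
#'
#' \code{homogeneityH} is \eqn{h = m_b / (\ln(2)\,E_b)}: for an
#' exponential distribution the median equals \eqn{\ln(2)} times the
#' mean, so \eqn{h = 1} indicates a one-pool-like, homogeneous system
#' and smaller values a heavier tail (the mean dominated by old carbon).
#' \code{homogeneityHPrime} is \eqn{h' = E_b / E_A}, the ratio of mean
#' backward transit time to mean system age, also 1 for a one-pool
#' system.
#'
#' @param mb median backward transit time (yr).
#' @param Eb mean backward transit time (yr), > 0.
#' @param EA mean system age (yr), > 0.
#' @return Dimensionless ratio.
#' @examples
#' homogeneityH(log(2) / 0.3, 1 / 0.3)  # exponential: exactly 1
#' @export
homogeneityH <- function(mb, Eb) {
  if (any(Eb <= 0)) stop("mean transit time must be > 0", call. = FALSE)
  mb / (log(2) * Eb)
}

#' @rdname homogeneityH
#' @export
homogeneityHPrime <- function(Eb, EA) {
  if (any(EA <= 0)) stop("mean system age must be > 0", call. = FALSE)
  Eb / EA
}

#' Aggregate backward transit-time distributions across sub-systems
#'
#' Pools the respiration-age densities of several cells (e.g. grid
#' cells of a spatial model) sharing one age grid and evaluation time:
#' mass densities and analytic tail scalars are summed, and the pooled
#' summaries recomputed from the summed density.  Aggregation acts on
#' mass-weighted densities, never on normalized pdfs, so total
#' respiration is conserved exactly and the pooled mean is the
#' respiration-weighted average of member means.
#'
#' @param cells list of \code{BTTDistribution} objects on identical age
#'   grids and times.
#' @param alphas quantile probabilities for the pooled summaries.
#' @return A pooled \code{BTTDistribution}.
#' @export
aggregateBTT <- function(cells, alphas = c(0.05, 0.5, 0.95)) {
  stopifnot(length(cells) >= 1L)
  a0 <- cells[[1]]$ages; t0 <- cells[[1]]$time
  for (c in cells[-1]) {
    if (length(c$ages) != length(a0) || any(c$ages != a0))
      stop("cells must share an identical age grid", call. = FALSE)
    if (!isTRUE(all.equal(c$time, t0)))
      stop("cells must share the evaluation time", call. = FALSE)
  }
  r <- Reduce(`+`, lapply(cells, `[[`, "density"))
  tailMass <- sum(vapply(cells, `[[`, 0, "tailMass"))
  tailAgeMoment <- sum(vapply(cells, `[[`, 0, "tailAgeMoment"))
  totals <- vapply(cells, `[[`, 0, "totalRespiration")
  total <- sum(totals)
  meanAge <- sum(totals * vapply(cells, `[[`, 0, "mean")) / total
  s <- bttSummarize(a0, r, total, meanAge,
                    sort(unique(c(alphas, 0.5))))
  structure(list(time = t0, ages = a0, density = r,
                 totalRespiration = s$total, pdf = r / s$total,
                 mean = s$mean, median = s$median,
                 quantiles = s$quantiles, tailMass = tailMass,
                 tailAgeMoment = tailAgeMoment),
            class = "BTTDistribution")
}

#' Homogeneity diagnostics of a scenario run
#'
#' Convenience extractor: the per-time diagnostics columns of a
#' [runScenario()] summary as a tidy frame.
#'
#' @param result a \code{ScenarioResult}.
#' @return data.frame with \code{time, Eb, mb, q95, EA, h, hPrime}.
#' @export
diagnosticsSeries <- function(result) {
  result$summary[, c("time", "Eb", "mb", "q95", "EA", "h", "hPrime")]
}
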