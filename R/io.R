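#' Read and write compartmental-system configurations
#'
#' Round-trippable system definitions: pool names, the compartmental
#' matrix B as nested lists (1/yr) and the input vector u (PgC/yr), in
#' JSON or YAML (chosen from the file extension).
#'
#' @param sys a [CompartmentalSystem-class].
#' @param path file path ending in \code{.json}, \code{.yml} or
#'   \code{.yaml}.
#' @return \code{readSystemConfig} returns a
#'   [CompartmentalSystem-class]; \code{writeSystemConfig} returns the
#'   path invisibly.
#' @export
writeSystemConfig <- function(sys, path) {
  obj <- list(poolNames = poolNames(sys),
              u = inputVector(sys),
              B = apply(compartmentalMatrix(sys), 1, as.list))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else stop("unsupported config format: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname writeSystemConfig
#' @export
readSystemConfig <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", path, call. = FALSE)
  B <- t(vapply(obj$B, function(row) unlist(row, use.names = FALSE),
                numeric(length(obj$u))))
  compartmentalSystem(u = unlist(obj$u), B = B,
                      poolNames = unlist(obj$poolNames))
}

#' Export a density on an age grid as CSV
#'
#' Column names carry the units: \code{age_yr} plus one column per pool
#' (or a single \code{density} column for scalar densities).
#'
#' @param density a \code{DensityOnAgeGrid} or \code{BTTDistribution}.
#' @param path output file.
#' @export
writeDensityCSV <- function(density, path) {
  if (inherits(density, "BTTDistribution")) {
    df <- data.frame(age_yr = density$ages,
                     density_PgC_per_yr2 = density$density,
                     pdf_per_yr = density$pdf)
  } else {
    v <- density$values
    if (is.matrix(v)) {
      df <- data.frame(age_yr = density$ages, t(v))
      names(df)[-1] <- rownames(v)
    } else df <- data.frame(age_yr = density$ages, density = v)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

writeManifest <- function(outDir, config, seed = NULL) {
  manifest <- list(
    package = "CarbonTransit",
    version = as.character(utils::packageVersion("CarbonTransit")),
    config = config, seed = seed,
    created = "see file mtime")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Equilibrium pipeline for the five-pool terrestrial model
#'
#' Writes the equilibrium transit-time density (with per-pool
#' decomposition), system-age and pool-age densities, and a JSON summary
#' of moments and quantiles to \code{outDir}.  Outputs are deterministic
#' and byte-identical across reruns.
#'
#' @param outDir output directory, created if needed.
#' @param sys system; defaults to [emanuelModel()].
#' @return Invisibly, the summary list.
#' @export
runEquilibriumPipeline <- function(outDir, sys = emanuelModel()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ss <- steadyState(sys)
  ages <- makeAgeGrid(sys)
  ft <- transitTimeDensity(sys, ages)
  mom <- transitTimeMoments(sys)
  qs <- transitTimeQuantile(sys, c(0.05, 0.5, 0.95))
  df <- data.frame(age_yr = ages,
                   respired_PgC_per_yr2 = ft$values * ss$total_input,
                   pdf_per_yr = ft$values, t(ft$byPool))
  utils::write.csv(df, file.path(outDir, "transit_time_density.csv"),
                   row.names = FALSE)
  writeDensityCSV(systemAgeDensity(sys, ss, ages),
                  file.path(outDir, "system_age_density.csv"))
  writeDensityCSV(poolAgeDensity(sys, ss, ages),
                  file.path(outDir, "pool_age_density.csv"))
  summary <- list(total_input_PgC_yr = ss$total_input,
                  total_stock_PgC = ss$total_stock,
                  mean_yr = mom$mean, sd_yr = mom$sd,
                  median_yr = qs[2], q05_yr = qs[1], q95_yr = qs[3])
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeManifest(outDir, list(pipeline = "equilibrium"))
  invisible(summary)
}

#' Scenario pipeline
#'
#' Runs one global-change scenario (see [runScenario()]) and writes the
#' tidy summary CSV (\code{time, GPP, Re, Eb, mb, q05, q95,
#' totalStock}), the diagnostics CSV (\code{time, Eb, mb, q95, EA, h,
#' hPrime}) and a JSON of headline percent changes.
#'
#' @inheritParams runScenario
#' @param outDir output directory.
#' @return Invisibly, the \code{ScenarioResult}.
#' @export
runScenarioPipeline <- function(outDir, which = c("co2", "temp", "both"),
                                sys = emanuelModel(), t0 = 1850,
                                tmax = 2020, by = 1) {
  which <- match.arg(which)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- runScenario(which, sys = sys, t0 = t0, tmax = tmax, by = by)
  utils::write.csv(res$summary[, c("time", "GPP", "Re", "Eb", "mb",
                                   "q05", "q95", "totalStock")],
                   file.path(outDir, paste0("summary_", which, ".csv")),
                   row.names = FALSE)
  utils::write.csv(diagnosticsSeries(res),
                   file.path(outDir, paste0("diagnostics_", which, ".csv")),
                   row.names = FALSE)
  pc <- percentChanges(res)
  jsonlite::write_json(
    list(scenario = which,
         pct_decrease_mean = pc[["mean"]],
         pct_decrease_median = pc[["median"]],
         pct_decrease_q95 = pc[["q95"]]),
    file.path(outDir, paste0("changes_", which, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeManifest(outDir, list(pipeline = "scenario", which = which,
                             t0 = t0, tmax = tmax, by = by))
  invisible(res)
}

#' Radiocarbon pipeline
#'
#' Runs the radiocarbon tracer through a scenario and through the
#' equilibrium reference with the same atmospheric curve, writing the
#' per-pool and respired Delta-14C series plus the
#' scenario-minus-equilibrium difference.
#'
#' @param outDir output directory.
#' @param which scenario flag as in [runScenario()].
#' @param curve an \code{AtmosphericC14Curve}; defaults to
#'   [syntheticBombCurve()].
#' @param sys base system.
#' @param t0,tmax span (yr).
#' @return Invisibly, a list with the scenario and reference
#'   \code{RadiocarbonRun}s and the difference frame.
#' @export
runRadiocarbonPipeline <- function(outDir, which = c("co2", "temp", "both"),
                                   curve = syntheticBombCurve(),
                                   sys = emanuelModel(), t0 = 1850,
                                   tmax = 2020) {
  which <- match.arg(which)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  times <- seq(t0, tmax, by = 1)
  tds <- globalChangeForcing(sys, co2On = which %in% c("co2", "both"),
                             tempOn = which %in% c("temp", "both"),
                             t0 = t0)
  run <- solveRadiocarbon(tds, curve, times)
  ref <- solveRadiocarbon(timeDependentSystem(sys, t0 = t0), curve, times)
  diff <- scenarioDeltaDifference(run, ref)
  df <- data.frame(year = times,
                   delta14c_atm = atmDelta14C(curve, times),
                   delta14c_resp = run$deltaResp, run$deltaPools,
                   check.names = FALSE)
  names(df)[-(1:3)] <- paste0("delta14c_", poolNames(sys))
  utils::write.csv(df, file.path(outDir, paste0("radiocarbon_", which,
                                                ".csv")),
                   row.names = FALSE)
  utils::write.csv(diff, file.path(outDir,
                                   paste0("radiocarbon_diff_", which,
                                          ".csv")),
                   row.names = FALSE)
  writeManifest(outDir, list(pipeline = "radiocarbon", which = which,
                             zone = curve$zone))
  invisible(list(run = run, reference = ref, difference = diff))
}
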