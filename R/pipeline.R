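#' Seasonal regional anomaly series
#'
#' Per-year regional summary of a seasonal window: for fluxes the sum of
#' the window months' regional integrals (PgC per season), for intensive
#' variables the regional area-weighted mean of the window-mean field.
#'
#' @param anoms an [AnomalyStack-class].
#' @param mask a [RegionMask-class].
#' @param window `"DecApr"` or `"MaySep"`.
#' @param dataset dataset id for the series.
#' @return An [AnnualAnomalySeries-class].
#' @export
seasonalRegionalSeries <- function(anoms, mask, window = c("MaySep", "DecApr"),
                                   dataset = "data") {
  window <- match.arg(window)
  mi <- .monthIndex(anoms@times)
  yy <- .years(anoms@times)
  years <- sort(unique(yy))
  years <- years[vapply(years, function(y) {
    want <- if (window == "DecApr") c(12L * (y - 1L) + 11L, 12L * y + 0:3) else 12L * y + 4:8
    all(want %in% mi)
  }, TRUE)]
  flux <- anoms@variable %in% .FLUX_VARS
  vals <- vapply(years, function(y) {
    f <- seasonalWindowMean(anoms, window, y)
    if (flux) regionalIntegrate(f, mask, "integral") * 5 / 1e15  # window sum, PgC
    else regionalIntegrate(f, mask, "mean")
  }, 0)
  annualAnomalySeries(dataset, mask@name, years, vals,
                      if (flux) "PgC season-1" else anoms@units)
}

#' Run the full synthetic-study pipeline
#'
#' Executes every analysis stage on a (generated) synthetic study: rotated
#' circulation modes from z500, DJF winter indices and tercile phase
#' classification, deseasonalized flux anomalies and regional annual
#' series, composite means with one-group and pairwise ANOVA, the EOF of
#' annual NBP fields on a common 1-degree grid, seasonal composite curves,
#' the ensemble envelope and the GPP-soil-water regression.  Optionally
#' writes CSV/NetCDF outputs and a JSON run manifest.
#'
#' @param config a `SyntheticConfig` (see [syntheticConfig()]).
#' @param outDir output directory, or `NULL` to skip writing files.
#' @param study an existing [simulateStudy()] result to analyse (default:
#'   generated from `config`).
#' @return List of class `PipelineResult` with elements `modes`,
#'   `assignment`, `membership`, `annualSeries`, `compositeTable`,
#'   `significance`, `pairwise`, `eof`, `curves`, `envelope`, `moisture`,
#'   `truth`, `manifest`.
#' @export
runPipeline <- function(config = syntheticConfig(), outDir = NULL, study = NULL) {
  if (is.null(study)) study <- simulateStudy(config)
  regions <- defaultRegions()
  g <- config$fluxGrid
  euMask <- buildRegionMask(regions$europe, g)
  stages <- character()

  # 1 circulation modes
  domain <- regionBox("north_atlantic", -90, 50, 20, 80)
  modes <- computeRotatedModes(study$z500, domain, months = c(12L, 1L, 2L),
                               nRetain = 2L)
  stages <- c(stages, "modes")

  # 2 winter indices and phase classification
  assignment <- classifyPhases(winterIndex(study$indices$nao),
                               winterIndex(study$indices$ea))
  membership <- compositeMembership(assignment)
  stages <- c(stages, "phases")

  # 3 anomalies and regional annual series
  memberNbpAnoms <- lapply(study$fluxes$members, function(m) deseasonalize(m$nbp))
  invAnoms <- lapply(study$fluxes$inversions, deseasonalize)
  annualSeries <- c(
    lapply(seq_along(memberNbpAnoms), function(i)
      regionalAnnualSeries(memberNbpAnoms[[i]], euMask, sprintf("dgvm%02d", i))),
    lapply(seq_along(invAnoms), function(i)
      regionalAnnualSeries(invAnoms[[i]], euMask, sprintf("inv%d", i))))
  stages <- c(stages, "anomalies")

  # 4 composite statistics (pooled member-years per group)
  isDgvm <- grepl("^dgvm", vapply(annualSeries, function(s) s@dataset, ""))
  poolValues <- function(seriesList, yrs) {
    unlist(lapply(seriesList, function(s) s@values[match(yrs, s@years)]))
  }
  compositeTable <- do.call(rbind, lapply(annualSeries, function(s) {
    cm <- compositeMean(s, membership)
    cm$dataset <- s@dataset
    cm
  }))
  significance <- do.call(rbind, lapply(names(membership), function(cc) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(dg) {
      v <- poolValues(annualSeries[isDgvm == dg], membership[[cc]])
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NULL)
      out <- compositeSignificance(v, cc)
      out$group <- if (dg) "dgvms" else "inversions"
      out
    }))
  }))
  nonNeutral <- setdiff(names(membership), "neutral")
  pairs <- utils::combn(nonNeutral, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- poolValues(annualSeries[isDgvm], membership[[a]])
    vb <- poolValues(annualSeries[isDgvm], membership[[b]])
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L) return(NULL)
    out <- compositePairwiseDifference(va, vb)
    out$pair <- paste(a, "vs", b)
    out
  }))
  stages <- c(stages, "composites")

  # 5 EOF of ensemble-mean annual NBP fields on a common 1-degree grid
  common <- gridSpec(seq(30.5, 73.5, 1), seq(-14.5, 58.5, 1))  # interior of the 2-deg domain
  yy <- .years(memberNbpAnoms[[1]]@times)
  years <- as.integer(names(table(yy))[table(yy) == 12L])
  meanAnom <- memberNbpAnoms[[1]]
  meanVals <- Reduce(`+`, lapply(memberNbpAnoms, function(a) a@values)) /
    length(memberNbpAnoms)
  meanStack <- monthlyFieldStack("NBP", meanVals, meanAnom@times, g,
                                 meanAnom@units)
  onCommon <- regridToCommon(meanStack, common)
  fields <- array(NA_real_, c(length(years), length(common@lat), length(common@lon)))
  for (i in seq_along(years)) fields[i, , ] <- annualIntegral(onCommon, years[i])
  eof <- nbpPca(fields, years, common)
  stages <- c(stages, "eof")

  # 6 curves, envelope, moisture dependence
  gppAnoms <- lapply(study$fluxes$members, function(m) deseasonalize(m$gpp))
  recoAnoms <- lapply(study$fluxes$members, function(m) deseasonalize(m$reco))
  ndviMonthly <- ndviMonthlyAnomalies(study$ndvi)
  curves <- seasonalFluxCurves(gppAnoms, recoAnoms, ndviMonthly, membership, euMask)
  envelope <- ensembleEnvelope(annualSeries[!isDgvm])
  moisture <- NULL
  if (!is.null(study$climate$SW)) {
    swAnoms <- deseasonalize(study$climate$SW)
    gppSummer <- seasonalRegionalSeries(gppAnoms[[1]], euMask, "MaySep", "dgvm01")
    swSummer <- seasonalRegionalSeries(swAnoms, euMask, "MaySep", "sw")
    moisture <- fluxMoistureDependence(gppSummer, swSummer)
  }
  stages <- c(stages, "curves")

  manifest <- list(
    package = "teleflux",
    version = as.character(utils::packageVersion("teleflux")),
    seed = config$seed, nYears = config$nYears,
    stages = stages, created = "run",
    configHash = sum(utf8ToInt(paste(deparse(config[
      c("nYears", "startYear", "seed", "rho", "beta")]), collapse = ""))))
  result <- list(modes = modes, assignment = assignment, membership = membership,
                 annualSeries = annualSeries, compositeTable = compositeTable,
                 significance = significance, pairwise = pairwise, eof = eof,
                 curves = curves, envelope = envelope, moisture = moisture,
                 truth = study$truth, manifest = manifest)
  class(result) <- "PipelineResult"
  if (!is.null(outDir)) writeResultBundle(result, outDir)
  result
}

#' Recover the injected phase effects from a synthetic flux ensemble
#'
#' Generates the indices and flux ensemble for a configuration, builds the
#' ensemble-mean continental annual NBP anomaly series, and estimates each
#' composite's effect as its mean anomaly relative to the neutral
#' composite (deseasonalization absorbs the period-mean of the injected
#' effects into the climatology, so the neutral-referenced contrast is the
#' unbiased estimator of the injected effect).  The analytic standard
#' error combines the generator's shared, member and pixel noise.
#'
#' @param config a `SyntheticConfig`.
#' @return data.frame with `composite`, `mean`, `n`, `estimate`, `se`,
#'   `beta` (the injected truth).
#' @export
recoverPhaseEffects <- function(config) {
  idx <- simulateModeIndices(config)
  fl <- simulateFluxEnsemble(config, idx$truth)
  mask <- buildRegionMask(defaultRegions()$europe, config$fluxGrid)
  series <- lapply(seq_along(fl$members), function(i)
    regionalAnnualSeries(deseasonalize(fl$members[[i]]$nbp), mask,
                         sprintf("dgvm%02d", i)))
  env <- ensembleEnvelope(series)
  ensSeries <- annualAnomalySeries("ensemble", "europe", env$year, env$mean)
  mem <- compositeMembership(idx$truth$assignment)
  cm <- compositeMean(ensSeries, mem)
  neutralMean <- cm$mean[cm$composite == "neutral"]
  aw <- cellAreas(config$fluxGrid) * mask@weights
  # NBP pixel noise = GPP minus RECO texture noise (independent draws)
  pixelVar <- 24 * config$pixelNoiseSd^2 * sum(aw^2) / 1e30
  varYear <- config$sharedNoiseSd^2 +
    (config$memberNoiseSd^2 + pixelVar) / config$nMembers
  nNeut <- cm$n[cm$composite == "neutral"]
  cm$estimate <- cm$mean - neutralMean
  cm$se <- sqrt(varYear * (1 / pmax(cm$n, 1) + 1 / nNeut))
  cm$beta <- unname(config$beta[cm$composite])
  cm
}

#' Write the tabular outputs of a pipeline run
#'
#' Phase assignment, composite means, significance, pairwise tests, curves,
#' envelope and the manifest, as CSV/JSON under `outDir`.
#'
#' @param result a `PipelineResult`.
#' @param outDir directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeResultBundle <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(phaseTable(result$assignment),
                   file.path(outDir, "phases.csv"), row.names = FALSE)
  utils::write.csv(result$compositeTable,
                   file.path(outDir, "composite_means.csv"), row.names = FALSE)
  utils::write.csv(result$significance,
                   file.path(outDir, "composite_significance.csv"), row.names = FALSE)
  if (!is.null(result$pairwise))
    utils::write.csv(result$pairwise,
                     file.path(outDir, "composite_pairwise.csv"), row.names = FALSE)
  utils::write.csv(result$curves, file.path(outDir, "seasonal_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(result$envelope, file.path(outDir, "envelope.csv"),
                   row.names = FALSE)
  if (!is.null(result$moisture))
    utils::write.csv(result$moisture, file.path(outDir, "gpp_sw_dependence.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Render summary figures of a pipeline run
#'
#' Composite bar chart of mean NBP anomalies per dataset, the ensemble
#' envelope time series, and the seasonal composite curves, written as a
#' single PDF.  Empty composites are annotated with `n = 0`.
#'
#' @param result a `PipelineResult`.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
makeReport <- function(result, path) {
  need <- c("compositeTable", "envelope", "curves")
  missing <- need[vapply(need, function(x) is.null(result[[x]]), TRUE)]
  if (length(missing)) .stopf("incomplete bundle: missing %s",
                              paste(missing, collapse = ", "))
  grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  ct <- result$compositeTable
  agg <- stats::aggregate(mean ~ composite, ct, mean, na.action = stats::na.omit)
  agg <- agg[match(.COMPOSITES, agg$composite), ]
  ns <- vapply(result$membership, length, 1L)
  graphics::barplot(agg$mean, names.arg = paste0(.COMPOSITES, "\n(n=", ns, ")"),
                    ylab = "mean NBP anomaly (PgC yr-1)",
                    main = "Composite NBP anomalies")
  env <- result$envelope
  graphics::plot(env$year, env$mean, type = "l", lwd = 2,
                 ylim = range(c(env$min, env$max), na.rm = TRUE),
                 xlab = "year", ylab = "NBP anomaly (PgC yr-1)",
                 main = "Ensemble envelope")
  graphics::polygon(c(env$year, rev(env$year)), c(env$min, rev(env$max)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(env$year, env$mean, lwd = 2)
  cv <- result$curves
  for (cc in unique(cv$composite)) {
    sub <- cv[cv$composite == cc & cv$variable %in% c("GPP", "RECO"), ]
    if (all(is.na(sub$mean))) next
    graphics::plot(NULL, xlim = c(1, 12), ylim = range(c(sub$min, sub$max), na.rm = TRUE),
                   xlab = "month", ylab = "regional anomaly (gC m-2 month-1)",
                   main = paste("Seasonal curves,", cc))
    for (vb in c("GPP", "RECO")) {
      s2 <- sub[sub$variable == vb, ]
      col <- if (vb == "GPP") "darkgreen" else "firebrick"
      graphics::polygon(c(s2$month, rev(s2$month)), c(s2$min, rev(s2$max)),
                        col = grDevices::adjustcolor(col, 0.3), border = NA)
      graphics::lines(s2$month, s2$mean, col = col, lwd = 2)
    }
  }
  invisible(path)
}
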