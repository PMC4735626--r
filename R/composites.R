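#' Composite means of an annual anomaly series
#'
#' Averages the series over the member years of each NAO-EA composite.
#' Years absent from the series (or masked) are dropped; empty composites
#' are reported with `NA` mean and `n = 0`.
#'
#' @param series an [AnnualAnomalySeries-class].
#' @param membership named list of member years, from
#'   [compositeMembership()].
#' @return data.frame with columns `composite`, `mean`, `n`.
#' @export
compositeMean <- function(series, membership) {
  rows <- lapply(names(membership), function(cc) {
    yrs <- intersect(membership[[cc]], series@years)
    v <- series@values[match(yrs, series@years)]
    v <- v[!is.na(v)]
    data.frame(composite = cc, mean = if (length(v)) mean(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Significance of a composite's mean anomaly
#'
#' Tests the null "the composite mean anomaly is zero" with a one-group
#' ANOVA against the zero reference: the F statistic is the squared
#' one-sample t, with p from F(1, n-1).  Member-year anomalies may be
#' pooled across the datasets of one group (inversions or DGVMs).
#'
#' @param values member-year anomalies (pooled across datasets of one
#'   group).
#' @param label composite label for bookkeeping.
#' @return data.frame with `composite`, `n`, `mean`, `sd`, `F`, `p`,
#'   `degenerate` (TRUE when within-composite variance is zero, where p is
#'   reported as 0 with the flag set).
#' @export
compositeSignificance <- function(values, label = "") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) .stopf("insufficient years: n = %d", n)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    return(data.frame(composite = label, n = n, mean = m, sd = 0,
                      F = if (m == 0) 0 else Inf, p = if (m == 0) 1 else 0,
                      degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  Fstat <- tstat^2
  data.frame(composite = label, n = n, mean = m, sd = s, F = Fstat,
             p = stats::pf(Fstat, 1, n - 1, lower.tail = FALSE),
             degenerate = FALSE)
}

#' Difference between two composites' mean anomalies
#'
#' Two-group one-way ANOVA (equal variance) for mean(A) = mean(B):
#' F equals the pooled-variance two-sample t squared, p from
#' F(1, nA + nB - 2).
#'
#' @param valuesA,valuesB member-year anomalies of the two composites.
#' @return data.frame with `F`, `p`, `nA`, `nB`, `degenerate`.
#' @export
compositePairwiseDifference <- function(valuesA, valuesB) {
  valuesA <- valuesA[!is.na(valuesA)]; valuesB <- valuesB[!is.na(valuesB)]
  nA <- length(valuesA); nB <- length(valuesB)
  if (nA < 2L || nB < 2L) .stopf("insufficient group size: nA = %d, nB = %d", nA, nB)
  if (stats::sd(valuesA) == 0 && stats::sd(valuesB) == 0) {
    same <- mean(valuesA) == mean(valuesB)
    return(data.frame(F = if (same) 0 else Inf, p = if (same) 1 else 0,
                      nA = nA, nB = nB, degenerate = TRUE))
  }
  ow <- stats::oneway.test(v ~ g,
                           data = data.frame(v = c(valuesA, valuesB),
                                             g = factor(rep(c("A", "B"), c(nA, nB)))),
                           var.equal = TRUE)
  data.frame(F = unname(ow$statistic), p = unname(ow$p.value),
             nA = nA, nB = nB, degenerate = FALSE)
}

#' Composite-mean climate anomaly maps
#'
#' For each composite, averages the seasonal-window-mean anomaly maps over
#' the member years — the map form of the phase-conditional climate
#' analysis (extended winter Dec-Apr or summer May-Sep).
#'
#' @param anoms an [AnomalyStack-class] of any registered climate variable.
#' @param membership named list from [compositeMembership()].
#' @param window `"DecApr"` or `"MaySep"`.
#' @return Named list of lat x lon matrices (all-`NA` for empty
#'   composites).
#' @export
climateCompositeFields <- function(anoms, membership, window = c("DecApr", "MaySep")) {
  window <- match.arg(window)
  d <- dim(anoms@values)
  mi <- .monthIndex(anoms@times)
  out <- lapply(names(membership), function(cc) {
    yrs <- membership[[cc]]
    yrs <- yrs[vapply(yrs, function(y) {
      want <- if (window == "DecApr") c(12L * (y - 1L) + 11L, 12L * y + 0:3) else 12L * y + 4:8
      all(want %in% mi)
    }, TRUE)]
    if (length(yrs) == 0L) return(matrix(NA_real_, d[2], d[3]))
    maps <- lapply(yrs, function(y) seasonalWindowMean(anoms, window, y))
    Reduce(`+`, maps) / length(maps)
  })
  names(out) <- names(membership)
  out
}

#' Seasonal composite curves of NDVI, GPP and respiration
#'
#' For each composite and calendar month: the regional mean monthly anomaly
#' averaged over member years, per ensemble member; reported as the
#' ensemble mean with a min-max envelope (GPP and RECO), plus the single
#' NDVI curve.
#'
#' @param gppList,recoList lists of [AnomalyStack-class] ensembles (one per
#'   member), sharing a span.
#' @param ndviMonthly an [AnomalyStack-class] of monthly NDVI anomalies
#'   (from [ndviMonthlyAnomalies()]), or `NULL`.
#' @param membership named list from [compositeMembership()].
#' @param mask regional [RegionMask-class].
#' @return data.frame with columns `composite`, `month`, `variable`
#'   (`GPP`, `RECO`, `NDVI`), `mean`, `min`, `max`.
#' @export
seasonalFluxCurves <- function(gppList, recoList, ndviMonthly = NULL,
                               membership, mask) {
  if (length(gppList) == 0L || length(recoList) == 0L) .stopf("empty ensemble")
  memberCurve <- function(anoms, yrs) {
    # 12-vector: regional mean anomaly per calendar month, averaged over years
    vapply(1:12, function(m) {
      r <- which(.months(anoms@times) == m & .years(anoms@times) %in% yrs)
      if (length(r) == 0L) return(NA_real_)
      mean(vapply(r, function(t)
        regionalIntegrate(anoms@values[t, , ], mask, "mean"), 0))
    }, 0)
  }
  rows <- list()
  for (cc in names(membership)) {
    yrs <- membership[[cc]]
    for (vb in c("GPP", "RECO")) {
      ens <- if (vb == "GPP") gppList else recoList
      if (length(yrs) == 0L) {
        curves <- matrix(NA_real_, length(ens), 12L)
      } else curves <- t(vapply(ens, memberCurve, numeric(12), yrs = yrs))
      rows[[length(rows) + 1L]] <- data.frame(
        composite = cc, month = 1:12, variable = vb,
        mean = colMeans(curves), min = apply(curves, 2, min),
        max = apply(curves, 2, max))
    }
    if (!is.null(ndviMonthly)) {
      nd <- if (length(yrs) == 0L) rep(NA_real_, 12L) else memberCurve(ndviMonthly, yrs)
      rows[[length(rows) + 1L]] <- data.frame(
        composite = cc, month = 1:12, variable = "NDVI",
        mean = nd, min = nd, max = nd)
    }
  }
  do.call(rbind, rows)
}

#' Cross-dataset envelope of annual anomaly series
#'
#' Per-year mean, minimum and maximum across datasets, honouring per-dataset
#' year masks (a dataset that does not cover a year is skipped for that
#' year).
#'
#' @param seriesList list of [AnnualAnomalySeries-class] objects for the
#'   same region.
#' @return data.frame with `year`, `mean`, `min`, `max`, `n` (datasets
#'   covering the year).
#' @export
ensembleEnvelope <- function(seriesList) {
  years <- sort(unique(unlist(lapply(seriesList, function(s) s@years))))
  rows <- lapply(years, function(y) {
    v <- unlist(lapply(seriesList, function(s) {
      i <- match(y, s@years)
      if (is.na(i)) NA_real_ else s@values[i]
    }))
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      data.frame(year = y, mean = NA_real_, min = NA_real_, max = NA_real_, n = 0L)
    else data.frame(year = y, mean = mean(v), min = min(v), max = max(v), n = length(v))
  })
  do.call(rbind, rows)
}

#' Dependence of summer GPP on soil water
#'
#' Ordinary least-squares regression of regional summer (May-Sep) GPP
#' anomalies on the matching soil-water anomalies: slope, Pearson r and
#' two-sided p — the regional moisture-control diagnostic.
#'
#' @param gppRegional,swRegional [AnnualAnomalySeries-class] objects of
#'   May-Sep regional anomalies.
#' @return data.frame with `slope`, `intercept`, `r`, `p`, `n`, `slopeSE`.
#' @export
fluxMoistureDependence <- function(gppRegional, swRegional) {
  years <- intersect(gppRegional@years, swRegional@years)
  g <- gppRegional@values[match(years, gppRegional@years)]
  s <- swRegional@values[match(years, swRegional@years)]
  keep <- !is.na(g) & !is.na(s)
  g <- g[keep]; s <- s[keep]
  if (length(g) < 5L) .stopf("need at least 5 common years, got %d", length(g))
  if (stats::sd(s) == 0) .stopf("degenerate regressor: zero soil-water variance")
  fit <- stats::lm(g ~ s)
  sm <- summary(fit)
  ct <- stats::cor.test(s, g)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r = unname(ct$estimate), p = ct$p.value, n = length(g),
             slopeSE = sm$coefficients[2, 2])
}
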