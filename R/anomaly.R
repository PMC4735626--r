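#' Remove the mean seasonal cycle from a monthly stack
#'
#' Computes the per-pixel, per-calendar-month mean over the base period and
#' subtracts it from every month, yielding monthly anomalies with the
#' climatology attached.
#'
#' @param stack a [MonthlyFieldStack-class].
#' @param basePeriod integer `c(firstYear, lastYear)` for the climatology;
#'   default the full span of the stack.
#' @return An [AnomalyStack-class].
#' @export
deseasonalize <- function(stack, basePeriod = NULL) {
  y <- .years(stack@times); m <- .months(stack@times)
  if (is.null(basePeriod)) basePeriod <- range(y)
  inBase <- y >= basePeriod[1] & y <= basePeriod[2]
  d <- dim(stack@values)
  clim <- array(NA_real_, c(12L, d[2], d[3]))
  for (mm in 1:12) {
    r <- which(inBase & m == mm)
    if (length(r) < 2L)
      .stopf("month %d has %d occurrence(s) in the base period; need at least 2", mm, length(r))
    clim[mm, , ] <- colMeans(stack@values[r, , , drop = FALSE], dims = 1)
  }
  anom <- stack@values - clim[m, , , drop = FALSE]
  new("AnomalyStack",
      variable = stack@variable, units = stack@units, times = stack@times,
      values = anom, grid = stack@grid,
      climatology = new("ClimatologyField", variable = stack@variable,
                        values = clim, grid = stack@grid,
                        basePeriod = as.integer(basePeriod)))
}

#' Annual integral of monthly anomalies
#'
#' Per-pixel sum of the twelve monthly anomalies of a calendar year
#' (units month-1 become yr-1).  Partial years are rejected.
#'
#' @param anoms an [AnomalyStack-class] (any [MonthlyFieldStack-class]
#'   works).
#' @param year calendar year.
#' @return lat x lon matrix of annual anomalies.
#' @export
annualIntegral <- function(anoms, year) {
  r <- which(.years(anoms@times) == year)
  if (length(r) != 12L) .stopf("incomplete year %d: %d month(s) present", year, length(r))
  colSums(anoms@values[r, , , drop = FALSE], dims = 1)
}

#' Seasonal window mean of monthly anomalies
#'
#' Per-pixel mean over the extended-winter window Dec-Apr (December taken
#' from the preceding calendar year) or the summer window May-Sep.
#'
#' @param anoms an [AnomalyStack-class].
#' @param window `"DecApr"` or `"MaySep"`.
#' @param year label year (the Jan-Apr / May-Sep year).
#' @return lat x lon matrix of window-mean anomalies.
#' @export
seasonalWindowMean <- function(anoms, window = c("DecApr", "MaySep"), year) {
  window <- match.arg(window)
  mi <- .monthIndex(anoms@times)
  want <- if (window == "DecApr") {
    c(12L * (year - 1L) + 11L, 12L * year + 0:3)
  } else 12L * year + 4:8
  r <- match(want, mi)
  if (any(is.na(r))) .stopf("incomplete window %s %d", window, year)
  colMeans(anoms@values[r, , , drop = FALSE], dims = 1)
}

#' Regionally integrate or average a field
#'
#' Integral mode (fluxes): \eqn{\sum v \cdot area \cdot w} over the mask,
#' giving e.g. gC month-1 from gC m-2 month-1 densities.  Mean mode
#' (intensive variables): area-weighted mean over the mask.  Masked (`NA`)
#' cells are excluded.
#'
#' @param field lat x lon matrix on the mask's grid.
#' @param mask a [RegionMask-class].
#' @param mode `"integral"` or `"mean"`.
#' @return Scalar.
#' @export
regionalIntegrate <- function(field, mask, mode = c("integral", "mean")) {
  mode <- match.arg(mode)
  if (!all(dim(field) == dim(mask@weights))) .stopf("field and mask grids differ")
  if (all(mask@weights == 0)) .stopf("empty region")
  aw <- cellAreas(mask@grid) * mask@weights
  keep <- !is.na(field) & aw > 0
  if (!any(keep)) return(NA_real_)
  if (mode == "integral") sum(field[keep] * aw[keep])
  else sum(field[keep] * aw[keep]) / sum(aw[keep])
}

#' Regionally integrated annual anomaly series for a flux stack
#'
#' Convenience wrapper: annual integrals of a deseasonalized flux stack,
#' regionally integrated and converted to PgC yr-1 (flux densities are
#' expected in gC m-2 month-1).
#'
#' @param anoms an [AnomalyStack-class] of a flux variable.
#' @param mask a [RegionMask-class].
#' @param dataset dataset identifier for the resulting series.
#' @param years years to evaluate (default all complete years).
#' @return An [AnnualAnomalySeries-class] in PgC yr-1.
#' @export
regionalAnnualSeries <- function(anoms, mask, dataset = "data", years = NULL) {
  yy <- .years(anoms@times)
  if (is.null(years)) {
    tab <- table(yy)
    years <- as.integer(names(tab)[tab == 12L])
  }
  vals <- vapply(years, function(y)
    regionalIntegrate(annualIntegral(anoms, y), mask, "integral") / 1e15, 0)
  annualAnomalySeries(dataset, mask@name, years, vals, "PgC yr-1")
}

#' Annual-integral NDVI anomalies from biweekly fields
#'
#' Per pixel, sums the 24 biweekly NDVI samples of each year and subtracts
#' the multi-year mean of those sums (departure from the average annual
#' integral).
#'
#' @param ndvi a [BiweeklyFieldStack-class] with complete 24-sample years.
#' @return List with `years` (integer) and `anomalies` (year x lat x lon
#'   array).
#' @export
integrateNdviAnnual <- function(ndvi) {
  yy <- .years(ndvi@times)
  years <- sort(unique(yy))
  cnt <- table(yy)
  if (any(cnt != 24L)) .stopf("incomplete year %s", names(cnt)[cnt != 24L][1])
  d <- dim(ndvi@values)
  integ <- array(NA_real_, c(length(years), d[2], d[3]))
  for (i in seq_along(years))
    integ[i, , ] <- colSums(ndvi@values[yy == years[i], , , drop = FALSE], dims = 1)
  clim <- colMeans(integ, dims = 1)
  anoms <- sweep(integ, c(2, 3), clim)
  list(years = years, anomalies = anoms)
}

#' Regional PDSI departure series
#'
#' Area-weighted regional mean of monthly PDSI minus its full-period time
#' mean — the drought diagnostic used where PDSI has a strong regional
#' dependence.
#'
#' @param pdsi a [MonthlyFieldStack-class] of variable `PDSI`.
#' @param mask a [RegionMask-class] on the same grid.
#' @return List with `times` and `values` (centred monthly series).
#' @export
pdsiRegionalDeparture <- function(pdsi, mask) {
  series <- vapply(seq_along(pdsi@times), function(t)
    regionalIntegrate(pdsi@values[t, , ], mask, "mean"), 0)
  list(times = pdsi@times, values = series - mean(series, na.rm = TRUE))
}

#' Average biweekly NDVI anomalies to monthly resolution
#'
#' Pairs the two samples of each calendar month, subtracts the per-pixel
#' per-calendar-month climatology, and returns a monthly anomaly stack —
#' the form needed for seasonal composite curves.
#'
#' @param ndvi a [BiweeklyFieldStack-class].
#' @return An [AnomalyStack-class] of monthly NDVI anomalies.
#' @export
ndviMonthlyAnomalies <- function(ndvi) {
  yy <- .years(ndvi@times); mm <- .months(ndvi@times)
  years <- sort(unique(yy))
  d <- dim(ndvi@values)
  vals <- array(NA_real_, c(length(years) * 12L, d[2], d[3]))
  times <- .monthSeq(years[1], 1L, length(years) * 12L)
  k <- 0L
  for (y in years) for (m in 1:12) {
    k <- k + 1L
    vals[k, , ] <- colMeans(ndvi@values[yy == y & mm == m, , , drop = FALSE], dims = 1)
  }
  stack <- monthlyFieldStack("NDVI", vals, times, ndvi@grid, units = "1")
  deseasonalize(stack)
}
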