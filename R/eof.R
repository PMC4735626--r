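#' Area-weighted PCA of annual NBP anomaly fields
#'
#' Decomposes a (year x lat x lon) stack of annual anomaly fields, after
#' multiplying anomalies by the square root of the normalized cos-latitude
#' weight, with an SVD over the spatial dimension.  Cells masked in any
#' year are excluded consistently.  PC1 is oriented to correlate positively
#' with the area-integrated (continental) series, so the positive phase
#' means a stronger sink for fluxes.
#'
#' @param fields numeric array (year, lat, lon) of annual anomalies on a
#'   common grid (resample first with [regridToCommon()] when datasets
#'   differ in resolution).
#' @param years integer years matching the first dimension.
#' @param grid the common [GridSpec-class].
#' @return An [EOFResult-class].
#' @export
nbpPca <- function(fields, years, grid) {
  d <- dim(fields)
  dec <- eofDecompose(fields, grid)
  sv <- dec$svd; ok <- dec$ok; w <- dec$w[ok]
  evAll <- dec$explainedVariance
  pc1 <- sv$u[, 1] * sv$d[1]
  eofW <- sv$v[, 1]

  # physical-space loading and continental orientation
  cont <- rowSums(sweep(matrix(fields, nrow = d[1])[, ok, drop = FALSE], 2,
                        as.vector(cellAreas(grid))[ok], "*"))
  if (stats::sd(cont) > 0 && stats::cor(pc1, cont) < 0) {
    pc1 <- -pc1; eofW <- -eofW
  }
  eofPhys <- rep(NA_real_, prod(d[2:3]))
  eofPhys[ok] <- eofW / sqrt(w)
  eof1 <- matrix(eofPhys, d[2], d[3])
  centers <- .findCenters(eof1, grid)
  new("EOFResult", eof1 = eof1, pc1 = as.numeric(pc1), years = as.integer(years),
      explainedVariance = evAll[1], allVariances = evAll,
      centers = centers$df, dipolar = centers$dipolar, grid = grid)
}

#' Full area-weighted EOF decomposition
#'
#' The SVD behind [nbpPca()], exposed for reconstruction and orthogonality
#' diagnostics: fields are centred over years, multiplied by the square
#' root of the normalized cos-latitude weights and decomposed.
#'
#' @param fields numeric array (year, lat, lon).
#' @param grid the [GridSpec-class].
#' @return List with `svd` (of the weighted centred matrix), `ok` (logical
#'   vector of retained cells), `w` (weight vector over all cells),
#'   `center` (per-cell means over years), `explainedVariance` (all
#'   modes).
#' @export
eofDecompose <- function(fields, grid) {
  d <- dim(fields)
  if (d[1] < 3L) .stopf("need at least 3 years, got %d", d[1])
  X <- matrix(fields, nrow = d[1])
  ok <- !apply(is.na(X), 2, any)
  if (!any(ok)) .stopf("all cells masked")
  ctr <- colMeans(X[, ok, drop = FALSE])
  X <- scale(X[, ok, drop = FALSE], center = TRUE, scale = FALSE)
  w <- as.vector(areaWeights(grid))
  Xw <- sweep(X, 2, sqrt(w[ok]), "*")
  sv <- svd(Xw)
  list(svd = sv, ok = ok, w = w, center = ctr,
       explainedVariance = sv$d^2 / sum(sv$d^2))
}

.findCenters <- function(map, grid) {
  if (all(is.na(map)) || diff(range(map, na.rm = TRUE)) == 0)
    .stopf("no centers: constant map")
  iMax <- which(map == max(map, na.rm = TRUE))[1]
  iMin <- which(map == min(map, na.rm = TRUE))[1]
  ij <- function(i) c((i - 1L) %% nrow(map) + 1L, (i - 1L) %/% nrow(map) + 1L)
  a <- ij(iMax); b <- ij(iMin)
  df <- data.frame(lat = c(grid@lat[a[1]], grid@lat[b[1]]),
                   lon = c(grid@lon[a[2]], grid@lon[b[2]]),
                   sign = c(sign(map[iMax]), sign(map[iMin])),
                   loading = c(map[iMax], map[iMin]))
  dipolar <- sign(map[iMax]) != sign(map[iMin]) && sign(map[iMax]) != 0
  list(df = df, dipolar = dipolar)
}

#' Centres of action of an EOF loading map
#'
#' Locations of the maximum and minimum loading.  When both extremes share
#' a sign the map is flagged non-dipolar.
#'
#' @param map lat x lon loading matrix.
#' @param grid the [GridSpec-class] the map lives on.
#' @return List with `centers` (data.frame: lat, lon, sign, loading) and
#'   `dipolar` (logical flag).
#' @export
centersOfAction <- function(map, grid) {
  res <- .findCenters(map, grid)
  list(centers = res$df, dipolar = res$dipolar)
}

#' Share of continental variance explained by a regional series
#'
#' Squared Pearson correlation between a regional and the continental
#' annual anomaly series, in percent — the "variance explained on average"
#' summary of how much a region drives the continental integral.
#'
#' @param regional,continental [AnnualAnomalySeries-class] objects (or bare
#'   numeric vectors of common years).
#' @return Percentage in \[0, 100\].
#' @export
regionalVarianceShare <- function(regional, continental) {
  if (is(regional, "AnnualAnomalySeries")) {
    years <- intersect(regional@years, continental@years)
    r <- regional@values[match(years, regional@years)]
    c0 <- continental@values[match(years, continental@years)]
  } else { r <- regional; c0 <- continental }
  keep <- !is.na(r) & !is.na(c0)
  r <- r[keep]; c0 <- c0[keep]
  if (length(r) < 3L) .stopf("need at least 3 common years")
  if (stats::sd(r) == 0 || stats::sd(c0) == 0) .stopf("zero-variance input")
  100 * stats::cor(r, c0)^2
}
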