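#' Rotated-PCA circulation modes from z500
#'
#' Computes varimax-rotated principal components of standardized monthly
#' 500-mb geopotential-height anomalies over an analysis domain (classically
#' 20-80 N, 90 W-50 E for the North Atlantic).  Anomalies are standardized
#' per pixel and calendar month, weighted by the square root of the
#' normalized cos-latitude area weight, decomposed by SVD, and the leading
#' `nRetain` modes varimax-rotated.  Amplitude series are re-standardized to
#' unit variance.  Mode signs follow the NAO convention: the northern centre
#' of action of each mode is negative in the mode's positive phase.
#'
#' @param z500 a [MonthlyFieldStack-class] of variable `Z500` covering the
#'   domain.
#' @param domain analysis [RegionBox-class].
#' @param months integer calendar months to analyse (default DJF =
#'   `c(12, 1, 2)`).
#' @param nRetain number of modes to retain and rotate (default 2 on
#'   synthetic dipole studies; the operational index procedure rotates 10).
#' @param rotate use varimax rotation (default) or return unrotated modes.
#' @param references optional list of reference patterns (lat x lon on the
#'   analysis domain, e.g. NAO and EA dipoles): modes are reordered to match
#'   them by maximal absolute congruence (rotation does not preserve
#'   variance ordering).
#' @details The returned loadings are regression maps: the physical
#'   (deseasonalized, unstandardized) anomaly regressed onto the
#'   standardized amplitude series, the conventional display of
#'   teleconnection patterns.  Explained variances refer to the
#'   standardized, area-weighted analysis space.
#' @return A [ModeSet-class].
#' @export
computeRotatedModes <- function(z500, domain, months = c(12L, 1L, 2L),
                                nRetain = 2L, rotate = TRUE, references = NULL) {
  stopifnot(is(z500, "MonthlyFieldStack"))
  g <- z500@grid
  inLat <- g@lat >= domain@latMin & g@lat <= domain@latMax
  inLon <- g@lon >= domain@lonMin & g@lon <= domain@lonMax
  if (!any(inLat) || !any(inLon)) .stopf("no overlap between z500 grid and domain")
  sel <- .months(z500@times) %in% months
  if (sum(sel) < 10L * length(months)) .stopf("need at least 10 years of selected months")
  sub <- z500@values[sel, inLat, inLon, drop = FALSE]
  times <- z500@times[sel]
  dg <- gridSpec(g@lat[inLat], g@lon[inLon])

  nt <- dim(sub)[1]; np <- prod(dim(sub)[2:3])
  Xphys <- matrix(sub, nrow = nt)  # columns are pixels (lat varying fastest)
  X <- Xphys
  mo <- .months(times)
  for (m in unique(mo)) {      # per-pixel per-calendar-month standardization
    r <- mo == m
    mu <- colMeans(X[r, , drop = FALSE])
    sd <- apply(X[r, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    Xphys[r, ] <- sweep(Xphys[r, , drop = FALSE], 2, mu)
    X[r, ] <- sweep(Xphys[r, , drop = FALSE], 2, sd, "/")
  }
  ok <- !apply(is.na(X), 2, any)
  if (!any(ok)) .stopf("all pixels masked in the analysis domain")
  w <- as.vector(areaWeights(dg))
  Xw <- sweep(X[, ok, drop = FALSE], 2, sqrt(w[ok]), "*")

  sv <- svd(Xw)
  totVar <- sum(sv$d^2)
  nAvail <- sum(sv$d > sv$d[1] * 1e-12)
  if (nRetain > nAvail) .stopf("nRetain = %d exceeds the %d available modes", nRetain, nAvail)
  k <- seq_len(nRetain)
  L <- sv$v[, k, drop = FALSE] %*% diag(sv$d[k] / sqrt(nt), nRetain)  # loadings
  A <- sv$u[, k, drop = FALSE] * sqrt(nt)                             # unit-variance scores

  rotation <- "none"
  if (rotate && nRetain > 1L) {
    vm <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
    R <- vm$rotmat
    L <- L %*% R
    A <- A %*% R
    rotation <- "varimax"
  }
  A <- scale(A, center = FALSE, scale = apply(A, 2, stats::sd))
  ev <- colSums(L^2) * nt / totVar

  # regression maps of the physical anomalies onto the amplitude series
  B <- qr.solve(A, Xphys[, ok, drop = FALSE])   # nRetain x pixels
  loadFull <- matrix(NA_real_, np, nRetain)
  loadFull[ok, ] <- t(B)

  # match modes to reference patterns by maximal absolute congruence
  if (!is.null(references)) {
    if (length(references) != nRetain)
      .stopf("need %d reference patterns, got %d", nRetain, length(references))
    cg <- vapply(seq_len(nRetain), function(m2)
      vapply(references, function(rf)
        abs(patternCongruence(loadFull[, m2], as.vector(rf), w)), 0),
      numeric(nRetain))          # ref x mode
    ord <- integer(nRetain)
    left <- seq_len(nRetain)
    for (rf in seq_len(nRetain)) {
      m2 <- left[which.max(cg[rf, left])]
      ord[rf] <- m2
      left <- setdiff(left, m2)
    }
    loadFull <- loadFull[, ord, drop = FALSE]
    A <- A[, ord, drop = FALSE]
    ev <- ev[ord]
  }

  # sign convention: northern centre of action negative in the positive phase
  latIdx <- rep(seq_len(dim(sub)[2]), times = dim(sub)[3])
  for (m2 in seq_len(nRetain)) {
    lv <- loadFull[, m2]
    iMax <- which.max(lv); iMin <- which.min(lv)
    northern <- if (dg@lat[latIdx[iMax]] >= dg@lat[latIdx[iMin]]) iMax else iMin
    if (!is.na(lv[northern]) && lv[northern] > 0) {
      loadFull[, m2] <- -loadFull[, m2]
      A[, m2] <- -A[, m2]
    }
  }
  loadings <- aperm(array(loadFull, c(dim(sub)[2], dim(sub)[3], nRetain)), c(3, 1, 2))
  new("ModeSet", loadings = loadings, amplitudes = unname(as.matrix(A)),
      times = times, explainedVariance = unname(ev), rotation = rotation, grid = dg)
}

#' Pattern congruence coefficient
#'
#' Tucker congruence between two spatial patterns (optionally area
#' weighted): \eqn{\sum w a b / \sqrt{\sum w a^2 \sum w b^2}} over cells
#' where both are defined.  Used to match recovered modes against reference
#' dipoles; the absolute value is sign-invariant.
#'
#' @param a,b numeric patterns of equal shape.
#' @param w optional weights (same shape).
#' @return Congruence in \[-1, 1\].
#' @export
patternCongruence <- function(a, b, w = NULL) {
  if (is.null(w)) w <- rep(1, length(a))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  sum(w * a * b) / sqrt(sum(w * a^2) * sum(w * b^2))
}

#' DJF winter means of a monthly index
#'
#' Averages December of year y-1 with January and February of year y and
#' labels the result with the January year, so winter 1982 = Dec 1981 + Jan
#' 1982 + Feb 1982.  A winter is reported only when at least two of its
#' three months are unmasked.
#'
#' @param series a [TeleconnectionSeries-class].
#' @return A [WinterIndexSeries-class].
#' @export
winterIndex <- function(series) {
  y <- .years(series@times); m <- .months(series@times)
  wy <- ifelse(m == 12L, y + 1L, y)
  keep <- m %in% c(12L, 1L, 2L)
  wy <- wy[keep]; v <- series@values[keep]
  years <- sort(unique(wy))
  # a winter needs all three months inside the series span
  lo <- .monthIndex(series@times[1]); hi <- .monthIndex(series@times[length(series@times)])
  full <- vapply(years, function(yy) {
    dec <- 12L * (yy - 1L) + 11L
    feb <- 12L * yy + 1L
    dec >= lo && feb <= hi
  }, TRUE)
  years <- years[full]
  if (length(years) == 0L) .stopf("series does not span a full DJF winter")
  vals <- vapply(years, function(yy) {
    x <- v[wy == yy]
    if (sum(!is.na(x)) >= 2L) mean(x, na.rm = TRUE) else NA_real_
  }, 0)
  new("WinterIndexSeries", name = series@name, winterYears = as.integer(years),
      values = vals)
}

#' Classify winters into joint NAO-EA phase composites
#'
#' Per-index empirical terciles are computed over the base period (linear
#' interpolation of order statistics, [stats::quantile()] type 7).  A winter
#' is `+` when its value strictly exceeds the upper tercile, `-` when
#' strictly below the lower tercile, else `0`; values exactly at a tercile
#' are neutral.  A winter enters one of the four non-neutral composites only
#' when both indices are non-zero; all other winters are `neutral`.
#'
#' @param nao,ea [WinterIndexSeries-class] objects covering the base period.
#' @param basePeriod integer length-2 `c(firstYear, lastYear)` over which
#'   terciles are computed; default the common span of the two series.
#' @return A [PhaseAssignment-class] for the winters common to both series.
#' @export
classifyPhases <- function(nao, ea, basePeriod = NULL) {
  years <- intersect(nao@winterYears, ea@winterYears)
  if (is.null(basePeriod)) basePeriod <- range(years)
  base <- years[years >= basePeriod[1] & years <= basePeriod[2]]
  if (length(base) < 9L) .stopf("too short for terciles: %d winters in base period", length(base))
  vn <- nao@values[match(years, nao@winterYears)]
  ve <- ea@values[match(years, ea@winterYears)]
  terc <- function(v) stats::quantile(v[years %in% base], c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  tn <- terc(vn); te <- terc(ve)
  phase <- function(v, t) ifelse(is.na(v), NA, ifelse(v > t[2], "+", ifelse(v < t[1], "-", "0")))
  pn <- phase(vn, tn); pe <- phase(ve, te)
  comp <- ifelse(is.na(pn) | is.na(pe), NA,
          ifelse(pn == "+" & pe == "+", "N+E+",
          ifelse(pn == "-" & pe == "-", "N-E-",
          ifelse(pn == "+" & pe == "-", "N+E-",
          ifelse(pn == "-" & pe == "+", "N-E+", "neutral")))))
  new("PhaseAssignment", winterYears = as.integer(years), nao = vn, ea = ve,
      naoPhase = pn, eaPhase = pe, composite = comp,
      thresholds = c(nao.lower = tn[1], nao.upper = tn[2],
                     ea.lower = te[1], ea.upper = te[2]))
}

#' Composite membership lists
#'
#' Splits the classified winters into five disjoint, exhaustive year lists,
#' one per composite (four joint phases plus neutral).
#'
#' @param assignment a [PhaseAssignment-class].
#' @return Named list of sorted integer year vectors, one entry per label in
#'   [compositeLabels()].
#' @export
compositeMembership <- function(assignment) {
  if (length(assignment@winterYears) == 0L) .stopf("empty assignment")
  out <- lapply(.COMPOSITES, function(cc)
    sort(assignment@winterYears[!is.na(assignment@composite) & assignment@composite == cc]))
  names(out) <- .COMPOSITES
  out
}

#' Longest consecutive run of anti-phase winters
#'
#' Finds the longest run of consecutive winters classified as either
#' anti-phase combination (NAO+EA- or NAO-EA+); ties are broken by the
#' earliest start.
#'
#' @param assignment a [PhaseAssignment-class].
#' @return List with `startYear` and `length` (length 0 when no anti-phase
#'   winter exists).
#' @export
longestAntiphaseRun <- function(assignment) {
  if (length(assignment@winterYears) == 0L) .stopf("empty assignment")
  ord <- order(assignment@winterYears)
  yrs <- assignment@winterYears[ord]
  anti <- assignment@composite[ord] %in% .ANTIPHASE
  best <- list(startYear = NA_integer_, length = 0L)
  i <- 1L
  while (i <= length(yrs)) {
    if (anti[i]) {
      j <- i
      while (j < length(yrs) && anti[j + 1L] && yrs[j + 1L] == yrs[j] + 1L) j <- j + 1L
      if (j - i + 1L > best$length) best <- list(startYear = yrs[i], length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

#' Export a PhaseAssignment as a data.frame
#'
#' Columns `winter_year`, `nao`, `ea`, `nao_phase`, `ea_phase`, `composite`
#' (the CSV layout of the external interface).
#'
#' @param assignment a [PhaseAssignment-class].
#' @return A data.frame, one row per winter.
#' @export
phaseTable <- function(assignment) {
  data.frame(winter_year = assignment@winterYears, nao = assignment@nao,
             ea = assignment@ea, nao_phase = assignment@naoPhase,
             ea_phase = assignment@eaPhase, composite = assignment@composite)
}
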