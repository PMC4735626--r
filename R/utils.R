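# small date/grid helpers shared across modules

.firstOfMonth <- function(d) as.Date(format(d, "%Y-%m-01"))

# months since year 0, for consecutiveness checks
.monthIndex <- function(d) {
  12L * as.integer(format(d, "%Y")) + as.integer(format(d, "%m")) - 1L
}

.monthSeq <- function(startYear, startMonth, n) {
  y <- startYear + (startMonth - 1 + seq_len(n) - 1) %/% 12
  m <- (startMonth - 1 + seq_len(n) - 1) %% 12 + 1
  as.Date(sprintf("%04d-%02d-01", y, m))
}

.years <- function(d) as.integer(format(d, "%Y"))
.months <- function(d) as.integer(format(d, "%m"))

# cell edges reconstructed as midpoints between centres; end cells get the
# same half-width as their neighbour
.cellBounds <- function(centers) {
  n <- length(centers)
  if (n == 1L) stop("cannot reconstruct bounds for a single-point axis without spacing")
  mids <- (centers[-n] + centers[-1]) / 2
  lower <- c(centers[1] - (mids[1] - centers[1]), mids)
  upper <- c(mids, centers[n] + (centers[n] - mids[n - 1]))
  cbind(lower = lower, upper = upper)
}

.cellBounds1 <- function(centers, spacing = NULL) {
  if (length(centers) > 1L) return(.cellBounds(centers))
  if (is.null(spacing)) stop("single-point axis needs explicit spacing")
  cbind(lower = centers - spacing / 2, upper = centers + spacing / 2)
}

# exact spherical cell areas (m^2) on a regular grid; latitude bands use
# sin-bounds so areas are additive under subdivision
.EARTH_RADIUS <- 6371008.8  # authalic mean radius, m

#' Cell areas of a regular grid
#'
#' Exact spherical areas \eqn{R^2 \Delta\lambda (\sin\phi_N - \sin\phi_S)}
#' per cell, with cell bounds reconstructed as midpoints between centres.
#' Areas are additive under subdivision, so conservative regridding and
#' regional integrals based on these areas conserve flux integrals to
#' machine precision.
#'
#' @param grid a [GridSpec-class].
#' @param latSpacing,lonSpacing explicit spacings (degrees), only needed for
#'   single-row/column grids.
#' @return lat x lon matrix of areas in m^2.
#' @export
cellAreas <- function(grid, latSpacing = NULL, lonSpacing = NULL) {
  lb <- .cellBounds1(grid@lat, latSpacing)
  lb[lb[, "lower"] < -90, "lower"] <- -90
  lb[lb[, "upper"] > 90, "upper"] <- 90
  band <- sin(lb[, "upper"] * pi / 180) - sin(lb[, "lower"] * pi / 180)
  dlon <- if (length(grid@lon) > 1L) diff(grid@lon)[1] else lonSpacing
  if (is.null(dlon)) stop("single-column grid needs explicit lonSpacing")
  outer(band, rep(dlon * pi / 180, length(grid@lon))) * .EARTH_RADIUS^2
}

# interval overlap length
.overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
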