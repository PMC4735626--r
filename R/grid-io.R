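#' Normalized cos-latitude area weights
#'
#' Weights proportional to the cosine of the cell-centre latitude,
#' normalized so the full grid sums to 1.  Used for area-weighted means and
#' for weighting anomalies prior to PCA.
#'
#' @param grid a [GridSpec-class].
#' @return lat x lon matrix of weights summing to 1.
#' @examples
#' g <- gridSpec(c(0, 60), c(0, 10))
#' areaWeights(g)  # 60N rows carry half the weight of equator rows
#' @export
areaWeights <- function(grid) {
  w <- outer(cos(grid@lat * pi / 180), rep(1, length(grid@lon)))
  w / sum(w)
}

#' Build a fractional region mask on a grid
#'
#' Computes, for every grid cell, the fraction of its lat-lon rectangle that
#' lies inside the region box; cells inside an exclusion box get that
#' fraction removed.  Cell bounds are reconstructed as midpoints between
#' centres.
#'
#' @param box a [RegionBox-class].
#' @param grid a [GridSpec-class].
#' @return A [RegionMask-class].
#' @examples
#' g <- gridSpec(seq(30.5, 70.5, 1), seq(-14.5, 59.5, 1))
#' m <- buildRegionMask(regionBox("iberia", -11, 3.5, 34, 44), g)
#' @export
buildRegionMask <- function(box, grid) {
  latB <- .cellBounds1(grid@lat)
  lonB <- .cellBounds1(grid@lon)
  frac <- function(b) {
    flat <- .overlap(latB[, 1], latB[, 2], b@latMin, b@latMax) / (latB[, 2] - latB[, 1])
    flon <- .overlap(lonB[, 1], lonB[, 2], b@lonMin, b@lonMax) / (lonB[, 2] - lonB[, 1])
    outer(flat, flon)
  }
  w <- frac(box)
  for (ex in box@exclusions) w <- w - frac(ex)
  w <- pmin(pmax(w, 0), 1)
  # snap floating-point residue from bound reconstruction
  w[w > 1 - 1e-9] <- 1
  w[w < 1e-9] <- 0
  if (all(w == 0)) .stopf("empty mask: region '%s' does not overlap the grid", box@name)
  new("RegionMask", grid = grid, name = box@name, weights = w)
}

# ---------------------------------------------------------------------------
# NetCDF I/O (CF style)
# ---------------------------------------------------------------------------

.NC_EPOCH <- as.Date("1850-01-01")
.NC_FILL <- 9.96920996838687e+36

#' Write a MonthlyFieldStack to CF-style NetCDF
#'
#' Axes `lon`, `lat`, unlimited `time` (days since 1850-01-01, standard
#' calendar); units and long_name attributes; masked cells encoded with the
#' CF default fill value.  Round-trips losslessly through
#' [readMonthlyNetcdf()].
#'
#' @param stack a [MonthlyFieldStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMonthlyNetcdf <- function(stack, path) {
  stopifnot(is(stack, "MonthlyFieldStack"))
  if (length(stack@times) == 0L) .stopf("empty stack")
  dLon <- ncdf4::ncdim_def("lon", "degrees_east", stack@grid@lon)
  dLat <- ncdf4::ncdim_def("lat", "degrees_north", stack@grid@lat)
  dTime <- ncdf4::ncdim_def("time", paste("days since", format(.NC_EPOCH)),
                            as.numeric(stack@times - .NC_EPOCH),
                            unlim = TRUE, calendar = "standard")
  v <- ncdf4::ncvar_def(stack@variable, stack@units, list(dLon, dLat, dTime),
                        missval = .NC_FILL, longname = stack@variable, prec = "double")
  nc <- ncdf4::nc_create(path, list(v))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, aperm(stack@values, c(3, 2, 1)))
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.6")
  invisible(path)
}

#' Read a MonthlyFieldStack from CF-style NetCDF
#'
#' Axes are normalised on read: latitude flipped to ascending if needed and
#' longitudes rotated onto the \[-180, 180) branch with the values permuted
#' consistently.  Time must decode to strictly consecutive calendar months.
#'
#' @param path NetCDF file path.
#' @param variable variable name in the file (must be in
#'   [registeredVariables()]).
#' @return A [MonthlyFieldStack-class].
#' @export
readMonthlyNetcdf <- function(path, variable) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!(variable %in% names(nc$var))) .stopf("variable not found: '%s'", variable)
  v <- nc$var[[variable]]
  dimnamesv <- vapply(v$dim, function(d) d$name, "")
  lonName <- dimnamesv[grep("^(lon|longitude)$", dimnamesv, ignore.case = TRUE)][1]
  latName <- dimnamesv[grep("^(lat|latitude)$", dimnamesv, ignore.case = TRUE)][1]
  timeName <- dimnamesv[grep("^time$", dimnamesv, ignore.case = TRUE)][1]
  if (any(is.na(c(lonName, latName, timeName)))) .stopf("need lon, lat and time axes")
  lon <- as.numeric(ncdf4::ncvar_get(nc, lonName))
  lat <- as.numeric(ncdf4::ncvar_get(nc, latName))
  tu <- ncdf4::ncatt_get(nc, timeName, "units")$value
  traw <- as.numeric(ncdf4::ncvar_get(nc, timeName))
  m <- regmatches(tu, regexec("^(days|hours|seconds) since ([0-9-]+)", tu))[[1]]
  if (length(m) == 0L) .stopf("cannot decode time units '%s'", tu)
  mult <- c(days = 1, hours = 1 / 24, seconds = 1 / 86400)[[m[2]]]
  times <- as.Date(m[3]) + round(traw * mult)
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  # put into (time, lat, lon) order
  perm <- match(c(timeName, latName, lonName), dimnamesv)
  vals <- aperm(array(vals, dim = vapply(v$dim, function(d) d$len, 1L)), perm)

  times <- .firstOfMonth(times)
  if (length(times) > 1L && any(diff(.monthIndex(times)) != 1L))
    .stopf("cadence error: time axis is not consecutive calendar months")
  if (length(lat) > 1L && lat[1] > lat[2]) {
    lat <- rev(lat); vals <- vals[, rev(seq_along(lat)), , drop = FALSE]
  }
  lon2 <- ifelse(lon >= 180, lon - 360, lon)
  ord <- order(lon2)
  lon2 <- lon2[ord]
  vals <- vals[, , ord, drop = FALSE]
  vals[abs(vals) > .NC_FILL / 2] <- NA  # belt-and-braces for fill decoding
  monthlyFieldStack(variable, vals, times, gridSpec(lat, lon2), units = v$units)
}

# ---------------------------------------------------------------------------
# Index tables (NOAA CPC dialect)
# ---------------------------------------------------------------------------

#' Read a monthly teleconnection index table
#'
#' Whitespace- or comma-delimited rows `year month value`, as in the NOAA
#' CPC monthly teleconnection tables; the CPC missing-value sentinel -99.9
#' is masked to `NA`.  Comment lines starting with `#` and blank lines are
#' skipped.
#'
#' @param path file path.
#' @param name index name to attach (default from file name).
#' @return A [TeleconnectionSeries-class].
#' @export
readIndexTable <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  yy <- mm <- vv <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    if (length(parts) < 3L) .stopf("parse error at line %d: need year month value", ln)
    num <- suppressWarnings(as.numeric(parts[1:3]))
    if (any(is.na(num))) .stopf("parse error at line %d: non-numeric field", ln)
    if (num[2] < 1 || num[2] > 12 || num[2] != round(num[2]))
      .stopf("parse error at line %d: month %s out of range", ln, parts[2])
    yy[i] <- num[1]; mm[i] <- num[2]; vv[i] <- num[3]
  }
  vv[vv == -99.9] <- NA
  teleconnectionSeries(name, sprintf("%04d-%02d-01", yy, mm), vv)
}

#' Write a TeleconnectionSeries in the CPC text dialect
#'
#' @param series a [TeleconnectionSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIndexTable <- function(series, path) {
  v <- series@values
  v[is.na(v)] <- -99.9
  writeLines(sprintf("%d %d %.2f", .years(series@times), .months(series@times), v), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Regridding
# ---------------------------------------------------------------------------

#' Regrid a stack to a common grid
#'
#' Flux variables (NBP, GPP, RECO) are remapped with first-order
#' conservative (area-overlap weighted) averaging of the surface densities,
#' which preserves the global area integral exactly; intensive variables are
#' remapped bilinearly (constant fields are reproduced).
#'
#' @param stack a [MonthlyFieldStack-class].
#' @param target target [GridSpec-class]; must overlap the source domain.
#' @param method `"auto"` (conservative for fluxes, bilinear otherwise),
#'   `"conservative"` or `"bilinear"`.
#' @param targetLatSpacing,targetLonSpacing explicit target cell sizes in
#'   degrees, required only when the target has a single row or column.
#' @return A [MonthlyFieldStack-class] on `target`.
#' @export
regridToCommon <- function(stack, target, method = c("auto", "conservative", "bilinear"),
                           targetLatSpacing = NULL, targetLonSpacing = NULL) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (stack@variable %in% .FLUX_VARS) "conservative" else "bilinear"
  src <- stack@grid
  sLat <- .cellBounds1(src@lat); sLon <- .cellBounds1(src@lon)
  tLat <- .cellBounds1(target@lat, targetLatSpacing)
  tLon <- .cellBounds1(target@lon, targetLonSpacing)
  if (max(sLat) < min(tLat) || min(sLat) > max(tLat) ||
      max(sLon) < min(tLon) || min(sLon) > max(tLon))
    .stopf("no overlap between source and target grids")
  nt <- length(stack@times)
  out <- array(NA_real_, c(nt, length(target@lat), length(target@lon)))

  if (method == "conservative") {
    # sparse row weights: overlap 'area' uses sin-lat bands so integrals are
    # conserved exactly
    sinS <- sin(sLat * pi / 180); sinT <- sin(tLat * pi / 180)
    wLat <- matrix(0, length(target@lat), length(src@lat))
    for (i in seq_along(target@lat))
      wLat[i, ] <- .overlap(sinS[, 1], sinS[, 2], sinT[i, 1], sinT[i, 2])
    wLon <- matrix(0, length(target@lon), length(src@lon))
    for (j in seq_along(target@lon))
      wLon[j, ] <- .overlap(sLon[, 1], sLon[, 2], tLon[j, 1], tLon[j, 2])
    for (t in seq_len(nt)) {
      f <- stack@values[t, , ]
      miss <- is.na(f)
      f0 <- ifelse(miss, 0, f)
      num <- wLat %*% f0 %*% t(wLon)
      den <- wLat %*% (1 - miss) %*% t(wLon)
      out[t, , ] <- ifelse(den > 0, num / den, NA)
    }
  } else {
    out[] <- .bilinearStack(stack@values, src, target)
  }
  monthlyFieldStack(stack@variable, out, stack@times, target, units = stack@units)
}

# bilinear interpolation of every time slice; outside the source hull the
# nearest edge value is used (constant extrapolation)
.bilinearStack <- function(vals, src, target) {
  nt <- dim(vals)[1]
  li <- .interpIndex(src@lat, target@lat)
  lj <- .interpIndex(src@lon, target@lon)
  out <- array(NA_real_, c(nt, length(target@lat), length(target@lon)))
  for (t in seq_len(nt)) {
    f <- vals[t, , ]
    f00 <- f[li$i0, lj$i0, drop = FALSE]; f01 <- f[li$i0, lj$i1, drop = FALSE]
    f10 <- f[li$i1, lj$i0, drop = FALSE]; f11 <- f[li$i1, lj$i1, drop = FALSE]
    wa <- outer(1 - li$w, 1 - lj$w); wb <- outer(1 - li$w, lj$w)
    wc <- outer(li$w, 1 - lj$w); wd <- outer(li$w, lj$w)
    out[t, , ] <- wa * f00 + wb * f01 + wc * f10 + wd * f11
  }
  out
}

.interpIndex <- function(srcAx, tgtAx) {
  i0 <- findInterval(tgtAx, srcAx, all.inside = TRUE)
  i1 <- pmin(i0 + 1L, length(srcAx))
  w <- ifelse(i1 > i0, (tgtAx - srcAx[i0]) / (srcAx[i1] - srcAx[i0]), 0)
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0, i1 = i1, w = w)
}
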