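#' @import methods
NULL

## Registry of gridded variables handled by the pipeline.  Fluxes are carried
## as surface densities (gC m-2 month-1); everything else is intensive.
.VAR_REGISTRY <- c("NBP", "GPP", "RECO", "Z500", "SLP", "T2M", "SW", "SD",
                   "CLOUD", "HT", "VT", "PDSI", "NDVI")
.FLUX_VARS <- c("NBP", "GPP", "RECO")

.COMPOSITES <- c("N+E+", "N-E-", "N+E-", "N-E+", "neutral")
.ANTIPHASE <- c("N+E-", "N-E+")

#' Registered gridded variables
#'
#' Names of the gridded variables the pipeline recognises: the carbon fluxes
#' (`NBP`, `GPP`, `RECO`), 500-mb geopotential height (`Z500`), sea-level
#' pressure (`SLP`), 2-m air temperature (`T2M`), volumetric soil water
#' (`SW`), snow depth (`SD`), cloud-cover fraction (`CLOUD`), eastward heat
#' and water-vapour transport (`HT`, `VT`) and the Palmer Drought Severity
#' Index (`PDSI`).
#'
#' @return Character vector of variable codes.
#' @export
registeredVariables <- function() .VAR_REGISTRY

#' Composite labels for joint NAO-EA phases
#'
#' @return Character vector: the four joint phase combinations plus
#'   `"neutral"`.
#' @export
compositeLabels <- function() .COMPOSITES

# ---------------------------------------------------------------------------
# GridSpec
# ---------------------------------------------------------------------------

#' GridSpec: a regular latitude-longitude grid
#'
#' Cell-centre registration; latitudes ascending in degrees north, longitudes
#' ascending in degrees east on the \[-180, 180) branch.  Spacing must be
#' uniform per axis (tolerance 1e-6 degrees); the two axes may differ.
#'
#' @slot lat numeric, ascending cell-centre latitudes.
#' @slot lon numeric, ascending cell-centre longitudes in \[-180, 180).
#' @export
setClass("GridSpec", representation(lat = "numeric", lon = "numeric"))

setValidity("GridSpec", function(object) {
  msgs <- character()
  for (ax in c("lat", "lon")) {
    v <- slot(object, ax)
    if (length(v) < 1L) msgs <- c(msgs, paste(ax, "axis is empty"))
    else {
      if (length(v) > 1L) {
        d <- diff(v)
        if (any(d <= 0)) msgs <- c(msgs, paste(ax, "axis not strictly ascending"))
        if (diff(range(d)) > 1e-6)
          msgs <- c(msgs, paste(ax, "spacing not uniform within 1e-6 degrees"))
      }
    }
  }
  if (any(abs(object@lat) > 90)) msgs <- c(msgs, "latitudes outside [-90, 90]")
  if (any(object@lon < -180 | object@lon >= 180))
    msgs <- c(msgs, "longitudes outside [-180, 180)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GridSpec
#'
#' @param lat ascending cell-centre latitudes (degrees north).
#' @param lon ascending cell-centre longitudes (degrees east, \[-180, 180)).
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(seq(-88.75, 88.75, by = 2.5), seq(-178.125, 178.125, by = 3.75))
#' @export
gridSpec <- function(lat, lon) new("GridSpec", lat = as.numeric(lat), lon = as.numeric(lon))

# ---------------------------------------------------------------------------
# Field stacks
# ---------------------------------------------------------------------------

#' MonthlyFieldStack: a monthly time x lat x lon gridded variable
#'
#' The universal carrier for flux and climate fields.  `values` is an array
#' with dimensions (time, lat, lon); `NA` encodes the missing-value mask.
#' Times are `Date`s pinned to the first of each month and must be strictly
#' consecutive calendar months.
#'
#' @slot variable one of [registeredVariables()].
#' @slot units unit string (e.g. `"gC m-2 month-1"`, `"gpm"`, `"mb"`).
#' @slot times `Date` vector, one per month, consecutive.
#' @slot values numeric array, dim = (time, lat, lon).
#' @slot grid a [GridSpec-class].
#' @export
setClass("MonthlyFieldStack",
         representation(variable = "character", units = "character",
                        times = "Date", values = "array", grid = "GridSpec"))

.checkStackGeometry <- function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array (time, lat, lon)")
  if (d[1] != length(object@times))
    msgs <- c(msgs, "time dimension does not match times")
  if (d[2] != length(object@grid@lat) || d[3] != length(object@grid@lon))
    msgs <- c(msgs, "spatial dimensions do not match grid")
  v <- object@values
  if (any(!is.na(v) & !is.finite(v)))
    msgs <- c(msgs, "non-finite unmasked values")
  msgs
}

setValidity("MonthlyFieldStack", function(object) {
  msgs <- .checkStackGeometry(object)
  if (!(object@variable %in% .VAR_REGISTRY))
    msgs <- c(msgs, paste0("unregistered variable '", object@variable, "'"))
  if (length(object@times) > 1L) {
    mi <- .monthIndex(object@times)
    if (any(diff(mi) != 1L)) msgs <- c(msgs, "times not strictly consecutive months")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MonthlyFieldStack
#'
#' @param variable variable code, see [registeredVariables()].
#' @param values numeric array (time, lat, lon); `NA` = masked.
#' @param times `Date` vector of consecutive months (any day-of-month; the
#'   day is normalised to 1).
#' @param grid a [GridSpec-class].
#' @param units unit string.
#' @return A [MonthlyFieldStack-class].
#' @export
monthlyFieldStack <- function(variable, values, times, grid, units = "") {
  times <- .firstOfMonth(as.Date(times))
  new("MonthlyFieldStack", variable = variable, units = units,
      times = times, values = values, grid = grid)
}

#' BiweeklyFieldStack: biweekly NDVI grids
#'
#' Like [MonthlyFieldStack-class] but with 24 samples per calendar year
#' (two per month, nominally the 1st and 15th) and the variable fixed to
#' NDVI, bounded in \[-1, 1\].
#'
#' @slot variable always `"NDVI"`.
#' @slot units dimensionless.
#' @slot times sample `Date`s, 24 per covered year.
#' @slot values numeric array (time, lat, lon).
#' @slot grid a [GridSpec-class].
#' @export
setClass("BiweeklyFieldStack",
         representation(variable = "character", units = "character",
                        times = "Date", values = "array", grid = "GridSpec"))

setValidity("BiweeklyFieldStack", function(object) {
  msgs <- .checkStackGeometry(object)
  if (object@variable != "NDVI") msgs <- c(msgs, "variable must be NDVI")
  yrs <- as.integer(format(object@times, "%Y"))
  if (any(table(yrs) != 24L)) msgs <- c(msgs, "each covered year needs exactly 24 samples")
  v <- object@values
  if (any(!is.na(v) & (v < -1 | v > 1))) msgs <- c(msgs, "NDVI values outside [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BiweeklyFieldStack
#'
#' @param values numeric array (time, lat, lon), 24 samples per year.
#' @param years integer vector of covered calendar years.
#' @param grid a [GridSpec-class].
#' @return A [BiweeklyFieldStack-class].
#' @export
biweeklyFieldStack <- function(values, years, grid) {
  times <- as.Date(unlist(lapply(years, function(y)
    paste0(y, "-", rep(sprintf("%02d", 1:12), each = 2), "-", c("01", "15")))))
  new("BiweeklyFieldStack", variable = "NDVI", units = "1",
      times = times, values = values, grid = grid)
}

# ---------------------------------------------------------------------------
# Regions
# ---------------------------------------------------------------------------

#' RegionBox: a rectangular latitude-longitude region
#'
#' Optionally with nested exclusion boxes (e.g. central Europe excluding
#' Great Britain).
#'
#' @slot name region name.
#' @slot lonMin,lonMax,latMin,latMax bounds in degrees.
#' @slot exclusions list of `RegionBox` to subtract; each must lie strictly
#'   inside the outer box.
#' @export
setClass("RegionBox",
         representation(name = "character", lonMin = "numeric", lonMax = "numeric",
                        latMin = "numeric", latMax = "numeric", exclusions = "list"))

setValidity("RegionBox", function(object) {
  msgs <- character()
  if (object@lonMin >= object@lonMax) msgs <- c(msgs, "lonMin must be < lonMax")
  if (object@latMin >= object@latMax) msgs <- c(msgs, "latMin must be < latMax")
  for (ex in object@exclusions) {
    if (!is(ex, "RegionBox")) { msgs <- c(msgs, "exclusions must be RegionBox"); next }
    if (ex@lonMin < object@lonMin || ex@lonMax > object@lonMax ||
        ex@latMin < object@latMin || ex@latMax > object@latMax)
      msgs <- c(msgs, paste0("exclusion '", ex@name, "' not inside the box"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionBox
#'
#' @param name region name.
#' @param lonMin,lonMax,latMin,latMax bounds in degrees east / north.
#' @param exclusions list of nested `RegionBox` objects to subtract.
#' @return A [RegionBox-class].
#' @examples
#' regionBox("iberia", -11, 3.5, 34, 44)
#' @export
regionBox <- function(name, lonMin, lonMax, latMin, latMax, exclusions = list()) {
  new("RegionBox", name = name, lonMin = lonMin, lonMax = lonMax,
      latMin = latMin, latMax = latMax, exclusions = exclusions)
}

#' RegionMask: fractional cell weights of a region on a grid
#'
#' @slot grid the [GridSpec-class] the mask lives on.
#' @slot name region name.
#' @slot weights lat x lon matrix in \[0, 1\]: fraction of each cell inside
#'   the region.
#' @export
setClass("RegionMask",
         representation(grid = "GridSpec", name = "character", weights = "matrix"))

setValidity("RegionMask", function(object) {
  msgs <- character()
  if (!all(dim(object@weights) == c(length(object@grid@lat), length(object@grid@lon))))
    msgs <- c(msgs, "weights dims do not match grid")
  w <- object@weights
  if (any(w < -1e-12 | w > 1 + 1e-12)) msgs <- c(msgs, "weights outside [0, 1]")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Index series / phases
# ---------------------------------------------------------------------------

#' TeleconnectionSeries: a monthly standardized circulation index
#'
#' @slot name index name, `"NAO"` or `"EA"` (free-form allowed for synthetic
#'   series).
#' @slot times `Date` vector of consecutive months.
#' @slot values standardized index values; `NA` = missing.
#' @export
setClass("TeleconnectionSeries",
         representation(name = "character", times = "Date", values = "numeric"))

setValidity("TeleconnectionSeries", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values lengths differ")
  if (length(object@times) > 1L && any(diff(.monthIndex(object@times)) != 1L))
    msgs <- c(msgs, "times not consecutive months")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TeleconnectionSeries
#'
#' @param name index name.
#' @param times month `Date`s (day normalised to 1).
#' @param values index values, `NA` allowed.
#' @return A [TeleconnectionSeries-class].
#' @export
teleconnectionSeries <- function(name, times, values) {
  new("TeleconnectionSeries", name = name,
      times = .firstOfMonth(as.Date(times)), values = as.numeric(values))
}

#' WinterIndexSeries: per-winter DJF means of an index
#'
#' Winters are labelled by the January year: December 1981 belongs to winter
#' 1982.  A winter value is present only when at least two of the three
#' months are unmasked.
#'
#' @slot name index name.
#' @slot winterYears integer years.
#' @slot values DJF means, `NA` where fewer than two months are available.
#' @export
setClass("WinterIndexSeries",
         representation(name = "character", winterYears = "integer", values = "numeric"))

setValidity("WinterIndexSeries", function(object) {
  if (length(object@winterYears) != length(object@values))
    "winterYears and values lengths differ" else TRUE
})

#' PhaseAssignment: joint NAO-EA phase classification of winters
#'
#' @slot winterYears integer winter labels (January year).
#' @slot nao,ea DJF index values.
#' @slot naoPhase,eaPhase `"+"`, `"-"` or `"0"` per winter.
#' @slot composite one of [compositeLabels()] per winter.
#' @slot thresholds named numeric: lower/upper terciles per index
#'   (`nao.lower`, `nao.upper`, `ea.lower`, `ea.upper`).
#' @export
setClass("PhaseAssignment",
         representation(winterYears = "integer", nao = "numeric", ea = "numeric",
                        naoPhase = "character", eaPhase = "character",
                        composite = "character", thresholds = "numeric"))

setValidity("PhaseAssignment", function(object) {
  n <- length(object@winterYears)
  msgs <- character()
  if (any(lengths(list(object@nao, object@ea, object@naoPhase,
                       object@eaPhase, object@composite)) != n))
    msgs <- c(msgs, "slot lengths differ")
  ok <- object@composite %in% .COMPOSITES | is.na(object@composite)
  if (!all(ok)) msgs <- c(msgs, "unknown composite label")
  nonneutral <- object@composite %in% .COMPOSITES[1:4]
  both <- object@naoPhase %in% c("+", "-") & object@eaPhase %in% c("+", "-")
  if (any(nonneutral != both, na.rm = TRUE))
    msgs <- c(msgs, "composite non-neutral iff both phases non-zero violated")
  th <- object@thresholds
  if (!is.na(th["nao.lower"]) && th["nao.lower"] >= th["nao.upper"])
    msgs <- c(msgs, "nao thresholds not ordered")
  if (!is.na(th["ea.lower"]) && th["ea.lower"] >= th["ea.upper"])
    msgs <- c(msgs, "ea thresholds not ordered")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Derived analysis objects
# ---------------------------------------------------------------------------

#' ClimatologyField: 12 per-calendar-month mean fields
#'
#' @slot variable variable code.
#' @slot values array (12, lat, lon) of calendar-month means.
#' @slot grid a [GridSpec-class].
#' @slot basePeriod integer length-2: first and last year of the base period.
#' @export
setClass("ClimatologyField",
         representation(variable = "character", values = "array",
                        grid = "GridSpec", basePeriod = "integer"))

setValidity("ClimatologyField", function(object) {
  if (dim(object@values)[1] != 12L) "climatology needs exactly 12 layers" else TRUE
})

#' AnomalyStack: a deseasonalized MonthlyFieldStack
#'
#' A [MonthlyFieldStack-class] whose values are departures from the attached
#' per-calendar-month climatology.
#'
#' @slot climatology the [ClimatologyField-class] that was removed.
#' @export
setClass("AnomalyStack", contains = "MonthlyFieldStack",
         representation(climatology = "ClimatologyField"))

#' AnnualAnomalySeries: regionally integrated annual anomalies
#'
#' Sign convention for fluxes: positive = enhanced sink.
#'
#' @slot dataset dataset identifier (e.g. `"inv1"`, `"dgvm03"`).
#' @slot region region name.
#' @slot years integer years.
#' @slot values annual anomalies (PgC yr-1 for fluxes; native units
#'   otherwise); `NA` where the dataset does not cover the year.
#' @slot units unit string.
#' @export
setClass("AnnualAnomalySeries",
         representation(dataset = "character", region = "character",
                        years = "integer", values = "numeric", units = "character"))

setValidity("AnnualAnomalySeries", function(object) {
  msgs <- character()
  if (length(object@years) != length(object@values))
    msgs <- c(msgs, "years and values lengths differ")
  if (length(object@years) > 1L && any(diff(object@years) != 1L))
    msgs <- c(msgs, "years not consecutive")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnualAnomalySeries
#' @param dataset,region identifiers.
#' @param years integer years (consecutive).
#' @param values annual anomaly values.
#' @param units unit string, default PgC yr-1.
#' @return An [AnnualAnomalySeries-class].
#' @export
annualAnomalySeries <- function(dataset, region, years, values, units = "PgC yr-1") {
  new("AnnualAnomalySeries", dataset = dataset, region = region,
      years = as.integer(years), values = as.numeric(values), units = units)
}

#' ModeSet: rotated-PCA circulation modes
#'
#' @slot loadings array (mode, lat, lon) of spatial patterns on the analysis
#'   domain (NA outside).
#' @slot amplitudes matrix (time, mode) of standardized amplitude series.
#' @slot times `Date`s of the analysed months.
#' @slot explainedVariance fraction of total anomaly variance per mode.
#' @slot rotation `"none"` or `"varimax"`.
#' @slot grid analysis-domain [GridSpec-class].
#' @export
setClass("ModeSet",
         representation(loadings = "array", amplitudes = "matrix", times = "Date",
                        explainedVariance = "numeric", rotation = "character",
                        grid = "GridSpec"))

setValidity("ModeSet", function(object) {
  msgs <- character()
  ev <- object@explainedVariance
  if (any(ev <= 0 | ev > 1 + 1e-12)) msgs <- c(msgs, "explained variances outside (0, 1]")
  if (sum(ev) > 1 + 1e-8) msgs <- c(msgs, "explained variances sum above 1")
  if (dim(object@loadings)[1] != ncol(object@amplitudes))
    msgs <- c(msgs, "mode count mismatch between loadings and amplitudes")
  if (length(msgs)) msgs else TRUE
})

#' EOFResult: leading mode of annual NBP anomaly fields
#'
#' @slot eof1 lat x lon loading map (area-weighted EOF, unit norm in the
#'   weighted inner product, mapped back to physical space).
#' @slot pc1 annual amplitude series.
#' @slot years integer years of `pc1`.
#' @slot explainedVariance fraction in (0, 1].
#' @slot allVariances explained-variance fractions of all computed modes.
#' @slot centers data.frame with columns lat, lon, sign for the two centres
#'   of action.
#' @slot dipolar logical: do the two extremes have opposite signs?
#' @slot grid the common-analysis [GridSpec-class].
#' @export
setClass("EOFResult",
         representation(eof1 = "matrix", pc1 = "numeric", years = "integer",
                        explainedVariance = "numeric", allVariances = "numeric",
                        centers = "data.frame", dipolar = "logical", grid = "GridSpec"))

setValidity("EOFResult", function(object) {
  ev <- object@explainedVariance
  if (length(ev) != 1L || ev <= 0 || ev > 1 + 1e-12)
    "explainedVariance must be a single fraction in (0, 1]" else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d lat x %d lon, lat %.2f..%.2f, lon %.2f..%.2f\n",
              length(object@lat), length(object@lon),
              min(object@lat), max(object@lat), min(object@lon), max(object@lon)))
})

setMethod("show", "MonthlyFieldStack", function(object) {
  cat(sprintf("%s of %s [%s]: %d months (%s..%s), %d x %d grid, %.1f%% masked\n",
              class(object), object@variable, object@units, length(object@times),
              format(object@times[1], "%Y-%m"),
              format(object@times[length(object@times)], "%Y-%m"),
              length(object@grid@lat), length(object@grid@lon),
              100 * mean(is.na(object@values))))
})

setMethod("show", "BiweeklyFieldStack", function(object) {
  cat(sprintf("BiweeklyFieldStack of NDVI: %d samples (%d years), %d x %d grid\n",
              length(object@times), length(object@times) %/% 24L,
              length(object@grid@lat), length(object@grid@lon)))
})

setMethod("show", "RegionBox", function(object) {
  cat(sprintf("RegionBox '%s': lon [%g, %g], lat [%g, %g], %d exclusion(s)\n",
              object@name, object@lonMin, object@lonMax, object@latMin,
              object@latMax, length(object@exclusions)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s' on %d x %d grid; %d cells with weight > 0\n",
              object@name, nrow(object@weights), ncol(object@weights),
              sum(object@weights > 0)))
})

setMethod("show", "TeleconnectionSeries", function(object) {
  cat(sprintf("TeleconnectionSeries %s: %d months (%s..%s), %d missing\n",
              object@name, length(object@times),
              format(object@times[1], "%Y-%m"),
              format(object@times[length(object@times)], "%Y-%m"),
              sum(is.na(object@values))))
})

setMethod("show", "WinterIndexSeries", function(object) {
  cat(sprintf("WinterIndexSeries %s: winters %d..%d (%d values, %d missing)\n",
              object@name, min(object@winterYears), max(object@winterYears),
              length(object@values), sum(is.na(object@values))))
})

setMethod("show", "PhaseAssignment", function(object) {
  tab <- table(factor(object@composite, levels = .COMPOSITES))
  cat("PhaseAssignment over", length(object@winterYears), "winters:\n")
  print(tab)
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet (%s): %d modes, explained variance %s\n",
              object@rotation, dim(object@loadings)[1],
              paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = ", ")))
})

setMethod("show", "EOFResult", function(object) {
  cat(sprintf("EOFResult: EOF1 explains %.1f%% over %d years; %s\n",
              100 * object@explainedVariance, length(object@years),
              if (object@dipolar) "dipolar" else "NON-dipolar"))
})

setMethod("show", "AnnualAnomalySeries", function(object) {
  cat(sprintf("AnnualAnomalySeries %s/%s: %d..%d [%s]\n", object@dataset,
              object@region, min(object@years), max(object@years), object@units))
})
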