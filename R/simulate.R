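#' Configuration for the synthetic study generator
#'
#' Builds the seeded configuration from which every input of the pipeline
#' can be generated, together with a truth ledger for parameter-recovery
#' tests.  Defaults emulate the study conditions of a 31-winter (1982-2012
#' analog) European analysis:
#'
#' * circulation: two orthogonal z500 dipoles (NAO-like and EA-like, the EA
#'   centres displaced south) with independent AR(1) amplitudes
#'   (`rho = 0.3`), pattern amplitude 40 gpm and pixel noise sd 30 gpm —
#'   the two modes then carry roughly three quarters of the winter
#'   variance, as the leading North-Atlantic modes do;
#' * fluxes: an 11-member pseudo-DGVM ensemble (plus 3 pseudo-inversions of
#'   NBP only) with smooth seasonal GPP/RECO cycles and annual continental
#'   NBP effects conditioned on the joint NAO-EA phase,
#'   `beta = +0.10 (N-E-), -0.05 (N+E-), -0.05 (N-E+), +0.02 (N+E+)`
#'   PgC yr-1, injected through GPP except for N-E+ which acts through a
#'   respiration rise; member-year noise 0.06 and shared interannual noise
#'   0.02 PgC yr-1 at continental scale, calibrated so the weakest
#'   prescribed contrast (anti-phase vs neutral, 0.05 PgC yr-1) is
#'   detectable with ~98% power from the 11-member, 31-winter design;
#' * soil water: a summer (May-Sep) regional moisture series coupled into
#'   GPP with slope 1.5 PgC per unit soil-water anomaly;
#' * NDVI: biweekly greenness tracking the GPP anomaly with configurable
#'   gain and additive noise, clipped to \[-1, 1\].
#'
#' @param nYears number of analysed years (>= 12).
#' @param startYear first analysed year; stacks start one year earlier so
#'   every winter has its December.
#' @param seed integer seed recorded in the truth ledger.
#' @param rho AR(1) coefficient of the mode amplitudes, in (-1, 1).
#' @param modeAmplitude z500 pattern amplitude (gpm).
#' @param zNoiseSd z500 pixel noise sd (gpm).
#' @param beta named numeric of continental NBP effect sizes per composite
#'   (PgC yr-1).
#' @param regionalBeta optional named list (region name from
#'   [defaultRegions()] -> named beta vector) of additional region-confined
#'   effects, injected on top of the continental ones.
#' @param gppShare named numeric in \[0, 1\]: fraction of each composite's
#'   NBP effect injected through GPP (remainder through a RECO change of
#'   opposite sign).
#' @param memberNoiseSd,sharedNoiseSd continental annual NBP noise sds
#'   (PgC yr-1): independent per member-year, and shared across members per
#'   year.
#' @param inversionNoiseSd continental annual noise sd of the
#'   pseudo-inversions (PgC yr-1).
#' @param pixelNoiseSd small-scale flux texture noise (gC m-2 month-1).
#' @param swGppSlope coupling of summer GPP to the regional soil-water
#'   anomaly (PgC per unit).
#' @param moistureSd sd of the annual summer moisture series (soil-water
#'   units, % volume).
#' @param ndviGain,ndviNoiseSd NDVI coupling gain (>= 0) and noise sd.
#' @param climateAmp,climateNoiseSd named per-variable pattern amplitudes
#'   and pixel noise sds for the phase-conditional climate stacks.
#' @param nMembers,nInversions ensemble sizes.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nYears = 31L, startYear = 1982L, seed = 1L,
                            rho = 0.3, modeAmplitude = 40, zNoiseSd = 30,
                            beta = c("N+E+" = 0.02, "N-E-" = 0.10,
                                     "N+E-" = -0.05, "N-E+" = -0.05,
                                     "neutral" = 0),
                            regionalBeta = NULL,
                            gppShare = c("N+E+" = 1, "N-E-" = 1,
                                         "N+E-" = 1, "N-E+" = 0, "neutral" = 1),
                            memberNoiseSd = 0.06, sharedNoiseSd = 0.02,
                            inversionNoiseSd = 0.10, pixelNoiseSd = 5,
                            swGppSlope = 1.5, moistureSd = 1,
                            ndviGain = 1, ndviNoiseSd = 0.02,
                            climateAmp = c(T2M = 2, SLP = 4, Z500 = 40, SW = 2,
                                           SD = 5, CLOUD = 8, HT = 30, VT = 20,
                                           PDSI = 1.5),
                            climateNoiseSd = c(T2M = 1, SLP = 2, Z500 = 20, SW = 1,
                                               SD = 2.5, CLOUD = 6, HT = 15, VT = 10,
                                               PDSI = 1),
                            nMembers = 11L, nInversions = 3L) {
  if (nYears < 12L) .stopf("nYears must be >= 12")
  if (abs(rho) >= 1) .stopf("rho must be in (-1, 1)")
  if (ndviGain < 0) .stopf("ndviGain must be >= 0")
  stopifnot(zNoiseSd >= 0, memberNoiseSd >= 0, sharedNoiseSd >= 0,
            all(is.finite(beta)))
  fluxGrid <- gridSpec(seq(31, 73, by = 2), seq(-14, 58, by = 2))
  z500Grid <- gridSpec(seq(21, 79, by = 2), seq(-89, 49, by = 2))
  cfg <- list(nYears = as.integer(nYears), startYear = as.integer(startYear),
              seed = as.integer(seed), rho = rho,
              modeAmplitude = modeAmplitude, zNoiseSd = zNoiseSd,
              beta = beta, regionalBeta = regionalBeta, gppShare = gppShare,
              memberNoiseSd = memberNoiseSd, sharedNoiseSd = sharedNoiseSd,
              inversionNoiseSd = inversionNoiseSd, pixelNoiseSd = pixelNoiseSd,
              swGppSlope = swGppSlope, moistureSd = moistureSd,
              ndviGain = ndviGain, ndviNoiseSd = ndviNoiseSd,
              climateAmp = climateAmp, climateNoiseSd = climateNoiseSd,
              nMembers = as.integer(nMembers), nInversions = as.integer(nInversions),
              fluxGrid = fluxGrid, z500Grid = z500Grid,
              naoCenters = list(pos = c(lat = 38, lon = -28), neg = c(lat = 66, lon = -28)),
              eaCenters = list(pos = c(lat = 28, lon = 8), neg = c(lat = 52, lon = -22)),
              modeWidth = 10)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Default analysis regions
#'
#' The continental European box (the full synthetic flux domain) and the
#' four large sub-regions: the Iberian Peninsula, continental central
#' Europe (with a Great-Britain exclusion box), western Russia / eastern
#' Europe, and Scandinavia.
#'
#' @return Named list of [RegionBox-class] objects.
#' @export
defaultRegions <- function() {
  list(
    europe = regionBox("europe", -15, 60, 30, 75),
    iberia = regionBox("iberia", -11, 3.5, 34, 44),
    central = regionBox("central", -5, 25, 44, 53,
                        exclusions = list(regionBox("great_britain", -5, 2, 50, 53))),
    russia = regionBox("russia", 29, 60, 46, 62),
    scandinavia = regionBox("scandinavia", 4.5, 29, 56, 71))
}

# Gaussian dipole on a grid: +1 bump minus -1 bump, lon distance scaled by
# cos(lat) so the bumps are roughly isotropic on the sphere
.dipolePattern <- function(grid, posC, negC, width) {
  bump <- function(cc) {
    dl <- outer(grid@lat - cc["lat"], rep(1, length(grid@lon)))
    dn <- outer(cos(grid@lat * pi / 180), grid@lon - cc["lon"])
    exp(-(dl^2 + dn^2) / (2 * width^2))
  }
  if (posC["lat"] < min(grid@lat) || posC["lat"] > max(grid@lat) ||
      negC["lat"] < min(grid@lat) || negC["lat"] > max(grid@lat) ||
      posC["lon"] < min(grid@lon) || posC["lon"] > max(grid@lon) ||
      negC["lon"] < min(grid@lon) || negC["lon"] > max(grid@lon))
    .stopf("pattern centers outside grid")
  bump(posC) - bump(negC)
}

#' True synthetic mode patterns
#'
#' The NAO-like and EA-like dipoles of the generator on the z500 grid,
#' area-weight orthogonalized (EA against NAO, Gram-Schmidt) and normalized
#' to unit weighted norm.  Sign convention: the northern centre is the
#' negative one, so a positive amplitude means the mode's positive phase.
#'
#' @param config a `SyntheticConfig`.
#' @return List with matrices `nao`, `ea` and the z500 [GridSpec-class].
#' @export
truthModePatterns <- function(config) {
  g <- config$z500Grid
  w <- areaWeights(g)
  nrm <- function(p) p / sqrt(sum(w * p^2))
  pn <- nrm(.dipolePattern(g, config$naoCenters$pos, config$naoCenters$neg,
                           config$modeWidth))
  pe <- .dipolePattern(g, config$eaCenters$pos, config$eaCenters$neg,
                       config$modeWidth)
  pe <- nrm(pe - sum(w * pe * pn) * pn)
  list(nao = pn, ea = pe, grid = g)
}

#' Simulate the two monthly teleconnection index series
#'
#' Two independent standardized AR(1) series (stationary variance 1),
#' starting January of `startYear - 1` so that every analysed winter has
#' its December, plus the truth ledger of the noise-free amplitudes and
#' the resulting true winter phases (tercile rule on the DJF means).
#'
#' @param config a `SyntheticConfig`.
#' @return List with `nao`, `ea` ([TeleconnectionSeries-class]) and
#'   `truth` (amplitude matrix, true [PhaseAssignment-class], membership).
#' @export
simulateModeIndices <- function(config) {
  nMonths <- (config$nYears + 1L) * 12L
  times <- .monthSeq(config$startYear - 1L, 1L, nMonths)
  set.seed(config$seed + 11L)
  ar1 <- function() {
    e <- stats::rnorm(nMonths)
    x <- numeric(nMonths)
    x[1] <- e[1]
    for (t in 2:nMonths)
      x[t] <- config$rho * x[t - 1] + sqrt(1 - config$rho^2) * e[t]
    x
  }
  aN <- ar1(); aE <- ar1()
  nao <- teleconnectionSeries("NAO", times, aN)
  ea <- teleconnectionSeries("EA", times, aE)
  assign <- classifyPhases(winterIndex(nao), winterIndex(ea))
  list(nao = nao, ea = ea,
       truth = list(amplitudes = cbind(NAO = aN, EA = aE), times = times,
                    assignment = assign, membership = compositeMembership(assign)))
}

#' Simulate the monthly z500 stack
#'
#' `z500(t, x) = amp * (A_NAO(t) P_NAO(x) + A_EA(t) P_EA(x)) + noise`, with
#' the orthogonal unit-norm dipoles of [truthModePatterns()] and iid pixel
#' noise.
#'
#' @param config a `SyntheticConfig`.
#' @param indices result of [simulateModeIndices()].
#' @return A [MonthlyFieldStack-class] of variable `Z500`.
#' @export
simulateZ500Stack <- function(config, indices) {
  pats <- truthModePatterns(config)
  amp <- indices$truth$amplitudes
  nMonths <- nrow(amp)
  g <- pats$grid
  set.seed(config$seed + 23L)
  vals <- array(stats::rnorm(nMonths * length(g@lat) * length(g@lon),
                             sd = config$zNoiseSd),
                c(nMonths, length(g@lat), length(g@lon)))
  for (t in seq_len(nMonths))
    vals[t, , ] <- vals[t, , ] + config$modeAmplitude *
      (amp[t, "NAO"] * pats$nao + amp[t, "EA"] * pats$ea)
  monthlyFieldStack("Z500", vals, indices$truth$times, g, units = "gpm")
}

# raised-cosine monthly weights over a month window, normalized to sum 1
.raisedCosine <- function(months) {
  k <- seq_along(months)
  w <- 1 - cos(2 * pi * k / (length(months) + 1))
  stats::setNames(w / sum(w), months)
}

#' Simulate the pseudo-DGVM flux ensemble and pseudo-inversions
#'
#' Each DGVM-like member carries GPP and RECO monthly density stacks
#' (gC m-2 month-1) built from smooth seasonal cycles, the
#' phase-conditional continental NBP effects (GPP effects spread as a
#' raised cosine over May-Sep, RECO effects over Jun-Aug), the summer
#' soil-moisture coupling into GPP, shared interannual noise, member noise
#' and pixel texture noise; `NBP = GPP - RECO` holds identically.
#' Inversions carry NBP only: the ensemble-mean NBP signal plus their own
#' noise.
#'
#' @param config a `SyntheticConfig`.
#' @param truth the truth ledger from [simulateModeIndices()] (provides the
#'   true composite of every winter).
#' @return List with `members` (list of `list(gpp, reco, nbp)`),
#'   `inversions` (list of NBP stacks), and `truth` additions (`moisture`,
#'   `effects` per year).
#' @export
simulateFluxEnsemble <- function(config, truth) {
  g <- config$fluxGrid
  regions <- defaultRegions()
  euMask <- buildRegionMask(regions$europe, g)
  aw <- cellAreas(g) * euMask@weights
  regionArea <- sum(aw)           # m^2
  inRegion <- euMask@weights > 0

  # effect specification: continental beta plus optional per-region betas
  effectSpec <- list(europe = config$beta)
  if (!is.null(config$regionalBeta)) {
    for (rn in names(config$regionalBeta)) {
      if (is.null(regions[[rn]])) .stopf("region '%s' not on grid", rn)
      effectSpec[[rn]] <- config$regionalBeta[[rn]]
    }
  }
  regionCells <- list(europe = inRegion)
  regionDensity <- list(europe = 1e15 / regionArea)
  for (rn in setdiff(names(effectSpec), "europe")) {
    mk <- buildRegionMask(regions[[rn]], g)
    regionCells[[rn]] <- mk@weights > 0
    regionDensity[[rn]] <- 1e15 / sum(cellAreas(g) * mk@weights)
  }
  nMonths <- (config$nYears + 1L) * 12L
  times <- .monthSeq(config$startYear - 1L, 1L, nMonths)
  yy <- .years(times); mm <- .months(times)
  nlat <- length(g@lat); nlon <- length(g@lon)

  # seasonal density cycles (gC m-2 month-1)
  gppCycle <- 20 + 80 * exp(-((1:12 - 7) / 2.2)^2)
  recoCycle <- 20 + 60 * exp(-((1:12 - 7.5) / 2.6)^2)

  # per-year injected NBP effect (PgC yr-1) from the true composite
  years <- config$startYear:(config$startYear + config$nYears - 1L)
  comp <- rep("neutral", length(years))
  idx <- match(years, truth$assignment@winterYears)
  comp[!is.na(idx)] <- truth$assignment@composite[idx[!is.na(idx)]]
  effect <- config$beta[comp]
  names(effect) <- years

  wG <- .raisedCosine(5:9)   # GPP effect months
  wR <- .raisedCosine(6:8)   # RECO effect months

  set.seed(config$seed + 37L)
  moisture <- stats::rnorm(config$nYears, sd = config$moistureSd)
  names(moisture) <- years
  sharedNoise <- stats::rnorm(config$nYears, sd = config$sharedNoiseSd)

  baseG <- array(rep(gppCycle[mm], nlat * nlon), c(nMonths, nlat, nlon))
  baseR <- array(rep(recoCycle[mm], nlat * nlon), c(nMonths, nlat, nlon))

  # deterministic signal arrays shared by all members
  sigG <- array(0, c(nMonths, nlat, nlon))
  sigR <- array(0, c(nMonths, nlat, nlon))
  addRegional <- function(arr, year, monthWeights, totalPgC,
                          cells = inRegion, dens = regionDensity$europe) {
    for (m in as.integer(names(monthWeights))) {
      t <- which(yy == year & mm == m)
      arr[t, , ][cells] <- arr[t, , ][cells] +
        totalPgC * monthWeights[[as.character(m)]] * dens
    }
    arr
  }
  for (i in seq_along(years)) {
    y <- years[i]
    for (rn in names(effectSpec)) {
      b <- effectSpec[[rn]][[comp[i]]]
      gs <- config$gppShare[[comp[i]]]
      if (b != 0) {
        if (gs != 0) sigG <- addRegional(sigG, y, wG, b * gs,
                                         regionCells[[rn]], regionDensity[[rn]])
        if (gs != 1) sigR <- addRegional(sigR, y, wR, -b * (1 - gs),
                                         regionCells[[rn]], regionDensity[[rn]])
      }
    }
    # summer moisture coupling: wet summers boost photosynthesis and
    # decomposition alike, so the coupling cancels in NBP and the net flux
    # stays governed by the phase effects; shared interannual noise enters
    # through GPP only and so persists in NBP
    sigG <- addRegional(sigG, y, wG,
                        config$swGppSlope * moisture[i] + sharedNoise[i])
    sigR <- addRegional(sigR, y, wG, config$swGppSlope * moisture[i])
  }

  memberStacks <- function(k) {
    # member-year continental noise, spread evenly over the 12 months
    yn <- stats::rnorm(config$nYears, sd = config$memberNoiseSd)
    flat <- stats::setNames(rep(1 / 12, 12), 1:12)
    noiseG <- array(0, c(nMonths, nlat, nlon))
    for (i in seq_along(years))
      noiseG <- addRegional(noiseG, years[i], flat, yn[i])
    px <- function() array(stats::rnorm(nMonths * nlat * nlon,
                                        sd = config$pixelNoiseSd),
                           c(nMonths, nlat, nlon))
    gpp <- baseG + sigG + noiseG + px()
    reco <- baseR + sigR + px()
    nbp <- gpp - reco
    list(gpp = monthlyFieldStack("GPP", gpp, times, g, "gC m-2 month-1"),
         reco = monthlyFieldStack("RECO", reco, times, g, "gC m-2 month-1"),
         nbp = monthlyFieldStack("NBP", nbp, times, g, "gC m-2 month-1"))
  }
  members <- lapply(seq_len(config$nMembers), memberStacks)

  meanNbp <- Reduce(`+`, lapply(members, function(m) m$nbp@values)) / config$nMembers
  inversions <- lapply(seq_len(config$nInversions), function(k) {
    yn <- stats::rnorm(config$nYears, sd = config$inversionNoiseSd)
    noise <- array(0, c(nMonths, nlat, nlon))
    for (i in seq_along(years))
      noise <- addRegional(noise, years[i],
                           stats::setNames(rep(1 / 12, 12), 1:12), yn[i])
    monthlyFieldStack("NBP", meanNbp + noise +
                        array(stats::rnorm(length(meanNbp), sd = config$pixelNoiseSd),
                              dim(meanNbp)),
                      times, g, "gC m-2 month-1")
  })

  list(members = members, inversions = inversions,
       truth = list(moisture = moisture, sharedNoise = sharedNoise,
                    effects = effect, effectSpec = effectSpec,
                    composites = stats::setNames(comp, years),
                    years = years))
}

#' Simulate the biweekly NDVI stack from a GPP stack
#'
#' Two samples per month: a baseline greenness cycle plus `gain` times the
#' (scaled) monthly GPP anomaly plus noise, clipped to \[-1, 1\].  The GPP
#' anomaly is taken against the per-calendar-month climatology of the
#' input stack.
#'
#' @param config a `SyntheticConfig`.
#' @param gpp a GPP [MonthlyFieldStack-class].
#' @return A [BiweeklyFieldStack-class].
#' @export
simulateNdviStack <- function(config, gpp) {
  if (config$ndviGain < 0) .stopf("ndviGain must be >= 0")
  anoms <- deseasonalize(gpp)
  yy <- .years(gpp@times)
  years <- sort(unique(yy))
  years <- years[vapply(years, function(y) sum(yy == y) == 12L, TRUE)]
  g <- gpp@grid
  nlat <- length(g@lat); nlon <- length(g@lon)
  baseline <- 0.3 + 0.25 * exp(-((1:12 - 7) / 2.5)^2)
  couplingScale <- 0.002  # NDVI units per gC m-2 month-1
  set.seed(config$seed + 51L)
  vals <- array(NA_real_, c(length(years) * 24L, nlat, nlon))
  k <- 0L
  for (y in years) for (m in 1:12) {
    t <- which(yy == y & .months(gpp@times) == m)
    sig <- baseline[m] + config$ndviGain * couplingScale * anoms@values[t, , ]
    for (s in 1:2) {
      k <- k + 1L
      vals[k, , ] <- sig + stats::rnorm(nlat * nlon, sd = config$ndviNoiseSd)
    }
  }
  vals <- pmin(pmax(vals, -1), 1)
  biweeklyFieldStack(vals, years, g)
}

# fixed per-composite climate pattern: a Gaussian anomaly at a
# composite-specific centre, sign alternating north/south for the
# anti-phase states so maps are distinguishable
.compositeClimatePattern <- function(grid, composite, amplitude) {
  centers <- list("N+E+" = c(lat = 60, lon = 10, s = 1),
                  "N-E-" = c(lat = 50, lon = 15, s = -1),
                  "N+E-" = c(lat = 65, lon = 35, s = 1),
                  "N-E+" = c(lat = 40, lon = 0, s = 1),
                  "neutral" = c(lat = 50, lon = 25, s = 0))
  cc <- centers[[composite]]
  if (is.null(cc)) .stopf("unknown composite '%s'", composite)
  dl <- outer(grid@lat - cc["lat"], rep(1, length(grid@lon)))
  dn <- outer(cos(grid@lat * pi / 180), grid@lon - cc["lon"])
  cc["s"] * amplitude * exp(-(dl^2 + dn^2) / (2 * 14^2))
}

#' Simulate a phase-conditional climate stack
#'
#' For each winter, the composite's prescribed anomaly pattern is active
#' during the extended-winter window months (Dec-Apr) on top of iid pixel
#' noise.  For `SW` the summer moisture series of the flux generator is
#' additionally added uniformly over the continental region during May-Sep,
#' so the GPP-soil-water regression has a recoverable slope.
#'
#' @param config a `SyntheticConfig`.
#' @param truth truth list carrying `assignment` (and `moisture` for `SW`,
#'   as returned by [simulateFluxEnsemble()]).
#' @param variable registered climate variable code.
#' @return A [MonthlyFieldStack-class].
#' @export
simulateClimateStack <- function(config, truth, variable) {
  if (!(variable %in% .VAR_REGISTRY)) .stopf("unregistered variable '%s'", variable)
  g <- config$fluxGrid
  nMonths <- (config$nYears + 1L) * 12L
  times <- .monthSeq(config$startYear - 1L, 1L, nMonths)
  yy <- .years(times); mm <- .months(times)
  amp <- config$climateAmp[[variable]]
  nsd <- config$climateNoiseSd[[variable]]
  if (is.null(amp) || is.na(amp)) .stopf("no pattern amplitude registered for '%s'", variable)
  set.seed(config$seed + 67L + match(variable, .VAR_REGISTRY))
  vals <- array(stats::rnorm(nMonths * length(g@lat) * length(g@lon), sd = nsd),
                c(nMonths, length(g@lat), length(g@lon)))
  pats <- lapply(.COMPOSITES, function(cc) .compositeClimatePattern(g, cc, amp))
  names(pats) <- .COMPOSITES
  asg <- truth$assignment
  for (i in seq_along(asg@winterYears)) {
    y <- asg@winterYears[i]
    cc <- asg@composite[i]
    if (is.na(cc) || cc == "neutral") next
    win <- which((yy == y - 1L & mm == 12L) | (yy == y & mm <= 4L))
    for (t in win) vals[t, , ] <- vals[t, , ] + pats[[cc]]
  }
  if (variable == "SW" && !is.null(truth$moisture)) {
    inRegion <- buildRegionMask(defaultRegions()$europe, g)@weights > 0
    for (y in as.integer(names(truth$moisture))) {
      win <- which(yy == y & mm %in% 5:9)
      for (t in win)
        vals[t, , ][inRegion] <- vals[t, , ][inRegion] +
          truth$moisture[[as.character(y)]]
    }
  }
  units <- c(T2M = "degC", SLP = "mb", Z500 = "gpm", SW = "% volume", SD = "cm",
             CLOUD = "%", HT = "MW km-1", VT = "g km-1 s-1", PDSI = "1")[[variable]]
  monthlyFieldStack(variable, vals, times, g, units = if (is.null(units)) "" else units)
}

#' Generate the complete synthetic study
#'
#' Runs every generator stage from one seeded configuration: indices,
#' z500, the flux ensemble, NDVI coupled to the first member's GPP, and
#' the requested climate stacks.  The returned `truth` ledger (amplitudes,
#' true phases, injected effects, moisture, config) is sufficient to
#' recompute every injected quantity from the seed.
#'
#' @param config a `SyntheticConfig`.
#' @param climateVars climate stacks to generate (default `T2M` and `SW`).
#' @return List with `indices`, `z500`, `fluxes`, `ndvi`, `climate` (named
#'   list), `truth`, `config`.
#' @export
simulateStudy <- function(config = syntheticConfig(),
                          climateVars = c("T2M", "SW")) {
  idx <- simulateModeIndices(config)
  z500 <- simulateZ500Stack(config, idx)
  fluxes <- simulateFluxEnsemble(config, idx$truth)
  truth <- c(idx$truth, fluxes$truth, list(config = config))
  ndvi <- simulateNdviStack(config, fluxes$members[[1]]$gpp)
  climate <- lapply(climateVars, function(v) simulateClimateStack(config, truth, v))
  names(climate) <- climateVars
  list(indices = idx[c("nao", "ea")], z500 = z500,
       fluxes = fluxes[c("members", "inversions")], ndvi = ndvi,
       climate = climate, truth = truth, config = config)
}
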