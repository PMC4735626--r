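test_that("composite means average member years and handle empty composites", {
  s <- annualAnomalySeries("inv1", "europe", 1990:1999, rep(0.7, 10))
  mem <- list("N+E+" = integer(0), "N-E-" = c(1996L, 1997L),
              "N+E-" = 1991L, "N-E+" = c(1993L, 1994L, 1995L),
              "neutral" = c(1990L, 1992L, 1998L, 1999L))
  cm <- compositeMean(s, mem)
  expect_equal(cm$mean[cm$composite != "N+E+"], rep(0.7, 4))
  expect_true(is.na(cm$mean[cm$composite == "N+E+"]))
  expect_identical(cm$n, c(0L, 2L, 1L, 3L, 4L))

  s2 <- annualAnomalySeries("inv1", "europe", 1996:1997, c(0.3, 0.5))
  cm2 <- compositeMean(s2, mem)
  expect_equal(cm2$mean[cm2$composite == "N-E-"], 0.4)
})

test_that("n-weighted composite means reconstruct the grand mean", {
  set.seed(40)
  years <- 1982:2012
  s <- annualAnomalySeries("d", "europe", years, rnorm(31))
  comp <- sample(compositeLabels(), 31, replace = TRUE)
  mem <- compositeMembership(makeAssignment(years, comp))
  cm <- compositeMean(s, mem)
  grand <- sum(cm$mean * cm$n, na.rm = TRUE) / sum(cm$n)
  expect_lt(abs(grand - mean(s@values)) / abs(mean(s@values)), 1e-10)
})

test_that("one-group significance equals the squared one-sample t", {
  # hand-computed: mean 0.25, sd 0.12910, n 4 -> t = 3.873, F = 15.0
  r <- compositeSignificance(c(0.4, 0.1, 0.3, 0.2), "N-E-")
  expect_equal(r$F, 15, tolerance = 1e-6)
  expect_equal(r$p, stats::pf(15, 1, 3, lower.tail = FALSE), tolerance = 1e-10)
  expect_false(r$degenerate)

  z <- compositeSignificance(c(-0.3, 0.3))
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)

  d <- compositeSignificance(c(1, 1, 1, 1))
  expect_true(d$degenerate)
  expect_equal(d$p, 0)

  expect_error(compositeSignificance(0.5), "insufficient years")

  # invariance under sign flip
  set.seed(41)
  for (rep in 1:25) {
    v <- rnorm(sample(3:12, 1))
    expect_equal(compositeSignificance(v)$p, compositeSignificance(-v)$p,
                 tolerance = 1e-12)
  }
})

test_that("pairwise composite difference equals the pooled two-sample t squared", {
  a <- c(0.1, 0.3); b <- c(-0.2, 0.0)
  r <- compositePairwiseDifference(a, b)
  # textbook pooled two-sample t
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(r$F, tstat^2, tolerance = 1e-10)
  expect_equal(r$p, stats::pf(tstat^2, 1, 2, lower.tail = FALSE), tolerance = 1e-10)

  same <- compositePairwiseDifference(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  dg <- compositePairwiseDifference(c(0, 0), c(1, 1))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 0)

  expect_error(compositePairwiseDifference(1, c(1, 2)), "insufficient group size")

  # symmetry in (A, B)
  set.seed(42)
  for (rep in 1:25) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    expect_equal(compositePairwiseDifference(x, y)$p,
                 compositePairwiseDifference(y, x)$p, tolerance = 1e-12)
  }
})

test_that("climate composite maps recover injected phase patterns", {
  cfg <- syntheticConfig(nYears = 16, seed = 51)
  idx <- simulateModeIndices(cfg)
  truth <- idx$truth

  # zero stack -> zero maps; single member year -> bitwise window mean
  stk <- simulateClimateStack(cfg, truth, "T2M")
  an <- deseasonalize(stk)
  mem <- compositeMembership(truth$assignment)
  maps <- climateCompositeFields(an, mem, "DecApr")
  oneYear <- names(mem)[vapply(mem, length, 1L) == 1L]
  for (cc in oneYear)
    expect_equal(maps[[cc]], seasonalWindowMean(an, "DecApr", mem[[cc]][1]),
                 tolerance = 1e-12)

  # a populated non-neutral composite to probe
  pops <- vapply(mem, length, 1L)
  cc0 <- names(which.max(pops[setdiff(names(pops), "neutral")]))
  expect_gte(pops[[cc0]], 2)

  zero <- monthlyFieldStack("T2M", array(0, dim(stk@values)), stk@times,
                            stk@grid, "degC")
  zmaps <- climateCompositeFields(deseasonalize(zero), mem, "DecApr")
  expect_equal(max(abs(zmaps[[cc0]]), na.rm = TRUE), 0)

  # pattern correlation with the injected anomaly at default noise
  inj <- teleflux:::.compositeClimatePattern(cfg$fluxGrid, cc0,
                                             cfg$climateAmp[["T2M"]])
  expect_gt(stats::cor(as.vector(maps[[cc0]]), as.vector(inj)), 0.9)
})

test_that("seasonal flux curves collapse for one member and respect NBP = GPP - RECO", {
  cfg <- syntheticConfig(nYears = 12, nMembers = 2, nInversions = 1, seed = 52)
  idx <- simulateModeIndices(cfg)
  fl <- simulateFluxEnsemble(cfg, idx$truth)
  mem <- compositeMembership(idx$truth$assignment)
  mask <- buildRegionMask(defaultRegions()$europe, cfg$fluxGrid)
  gppA <- lapply(fl$members, function(m) deseasonalize(m$gpp))
  recoA <- lapply(fl$members, function(m) deseasonalize(m$reco))
  cv <- seasonalFluxCurves(gppA[1], recoA[1], NULL, mem, mask)
  expect_equal(cv$mean, cv$min, tolerance = 1e-12)
  expect_equal(cv$mean, cv$max, tolerance = 1e-12)

  # month-wise NBP curve = GPP curve - RECO curve
  nbpA <- lapply(fl$members, function(m) deseasonalize(m$nbp))
  cvAll <- seasonalFluxCurves(gppA, recoA, NULL, mem, mask)
  cvN <- seasonalFluxCurves(nbpA, recoA, NULL, mem, mask)  # GPP slot holds NBP
  for (cc in compositeLabels()) {
    if (length(mem[[cc]]) == 0) next
    gm <- cvAll$mean[cvAll$composite == cc & cvAll$variable == "GPP"]
    rm_ <- cvAll$mean[cvAll$composite == cc & cvAll$variable == "RECO"]
    nm <- cvN$mean[cvN$composite == cc & cvN$variable == "GPP"]
    expect_equal(nm, gm - rm_, tolerance = 1e-10)
  }
  expect_error(seasonalFluxCurves(list(), list(), NULL, mem, mask),
               "empty ensemble")
})

test_that("growing-season GPP enhancement shows up only in summer months", {
  cfg <- syntheticConfig(nYears = 20, nMembers = 3, seed = 53,
                         memberNoiseSd = 0.01, sharedNoiseSd = 0,
                         pixelNoiseSd = 0.5, swGppSlope = 0)
  idx <- simulateModeIndices(cfg)
  fl <- simulateFluxEnsemble(cfg, idx$truth)
  mem <- compositeMembership(idx$truth$assignment)
  mask <- buildRegionMask(defaultRegions()$europe, cfg$fluxGrid)
  gppA <- lapply(fl$members, function(m) deseasonalize(m$gpp))
  recoA <- lapply(fl$members, function(m) deseasonalize(m$reco))
  cv <- seasonalFluxCurves(gppA, recoA, NULL, mem, mask)
  gcurve <- cv[cv$composite == "N-E-" & cv$variable == "GPP", ]
  # effect confined to May-Sep: summer positive, deep winter near zero
  expect_gt(mean(gcurve$mean[gcurve$month %in% 6:8]), 0)
  expect_gt(max(gcurve$mean[gcurve$month %in% 5:9]),
            5 * max(abs(gcurve$mean[gcurve$month %in% c(12, 1, 2, 3)])))
})

test_that("ensemble envelopes honour per-dataset coverage", {
  a <- annualAnomalySeries("a", "europe", 2000:2002, c(0.2, 0.1, 0.0))
  b <- annualAnomalySeries("b", "europe", 2000:2001, c(-0.4, 0.3))
  env <- ensembleEnvelope(list(a, b))
  expect_equal(env$mean[env$year == 2000], -0.1)
  expect_equal(env$min[env$year == 2000], -0.4)
  expect_equal(env$max[env$year == 2000], 0.2)
  expect_identical(env$n, c(2L, 2L, 1L))
  # staggered end year: 2002 uses only dataset a
  expect_equal(env$mean[env$year == 2002], 0.0)
  expect_equal(env$min[env$year == 2002], env$max[env$year == 2002])

  solo <- ensembleEnvelope(list(a))
  expect_equal(solo$mean, solo$min)
  expect_equal(solo$mean, solo$max)
})

test_that("GPP-soil-water regression recovers exact, null and noisy couplings", {
  years <- 1991:2010
  set.seed(60)
  sw <- rnorm(20)
  exact <- suppressWarnings(fluxMoistureDependence(    # perfect-fit notice
    annualAnomalySeries("g", "r", years, 2 * sw),
    annualAnomalySeries("s", "r", years, sw)))
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$r, 1, tolerance = 1e-10)

  # independent series, n = 1000 -> |r| < 0.1
  yrs2 <- 1001:2000
  ind <- fluxMoistureDependence(
    annualAnomalySeries("g", "r", yrs2, rnorm(1000)),
    annualAnomalySeries("s", "r", yrs2, rnorm(1000)))
  expect_lt(abs(ind$r), 0.1)

  # noisy coupling (noise sd = signal sd): the 2-SE interval covers the
  # true slope at its nominal ~95% rate over replicates
  covered <- 0
  for (rep in 1:20) {
    x <- rnorm(200)
    y <- 1.5 * x + rnorm(200, sd = 1.5 * stats::sd(x))
    noisy <- fluxMoistureDependence(
      annualAnomalySeries("g", "r", 1:200 + 1800, y),
      annualAnomalySeries("s", "r", 1:200 + 1800, x))
    covered <- covered + (abs(noisy$slope - 1.5) < 2 * noisy$slopeSE)
  }
  expect_gte(covered, 17)

  expect_error(fluxMoistureDependence(
    annualAnomalySeries("g", "r", years, rnorm(20)),
    annualAnomalySeries("s", "r", years, rep(1, 20))), "degenerate regressor")
  expect_error(fluxMoistureDependence(
    annualAnomalySeries("g", "r", 2000:2003, rnorm(4)),
    annualAnomalySeries("s", "r", 2000:2003, rnorm(4))), "at least 5")
})
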