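test_that("deseasonalization removes cycles and matches a two-pass loop oracle", {
  g <- tinyGrid()
  times <- seq(as.Date("2000-01-01"), by = "month", length.out = 48)
  cyc <- sin(2 * pi * (1:12) / 12)
  vals <- array(0, c(48, 3, 4))
  for (t in 1:48) vals[t, , ] <- cyc[(t - 1) %% 12 + 1]
  pure <- monthlyFieldStack("NBP", vals, times, g)
  expect_equal(max(abs(deseasonalize(pure)@values)), 0, tolerance = 1e-12)

  cst <- monthlyFieldStack("NBP", array(3.7, c(48, 3, 4)), times, g)
  expect_equal(max(abs(deseasonalize(cst)@values)), 0, tolerance = 1e-12)

  stk <- randomMonthlyStack("NBP", nMonths = 48, seed = 8)
  an <- deseasonalize(stk)
  # naive loop: accumulate month means, subtract
  mo <- as.integer(format(stk@times, "%m"))
  for (i in 1:3) for (j in 1:4) for (m in 1:12) {
    r <- which(mo == m)
    mu <- sum(stk@values[r, i, j]) / length(r)
    expect_equal(an@values[r, i, j], stk@values[r, i, j] - mu, tolerance = 1e-12)
  }
  # residual climatology of the anomalies is numerically zero
  an2 <- deseasonalize(monthlyFieldStack("NBP", an@values, an@times, g))
  expect_lt(max(abs(an2@climatology@values)), 1e-10 * stats::sd(stk@values))
})

test_that("deseasonalization rejects base periods missing a month", {
  stk <- randomMonthlyStack("NBP", nMonths = 15, seed = 9)  # months 4..12 appear once
  expect_error(deseasonalize(stk), "month")
})

test_that("annual integral is the 12-month sum and rejects partial years", {
  g <- tinyGrid()
  times <- seq(as.Date("2000-01-01"), by = "month", length.out = 24)
  a <- 0.25
  stk <- monthlyFieldStack("NBP", array(a, c(24, 3, 4)), times, g)
  an <- new("AnomalyStack", stk,
            climatology = new("ClimatologyField", variable = "NBP",
                              values = array(0, c(12, 3, 4)), grid = g,
                              basePeriod = c(2000L, 2001L)))
  expect_equal(annualIntegral(an, 2000), matrix(12 * a, 3, 4), tolerance = 1e-12)

  rnd <- randomMonthlyStack("NBP", nMonths = 24, seed = 10)
  yi <- annualIntegral(rnd, 2001)
  for (i in 1:3) for (j in 1:4)
    expect_equal(yi[i, j], sum(rnd@values[13:24, i, j]), tolerance = 1e-12)
  expect_error(annualIntegral(randomMonthlyStack(nMonths = 18), 2001),
               "incomplete year")
})

test_that("centred anomalies have near-zero mean annual integrals over the base period", {
  stk <- randomMonthlyStack("NBP", nMonths = 72, seed = 12)
  an <- deseasonalize(stk)
  sums <- sapply(2000:2005, function(y) annualIntegral(an, y))
  expect_lt(max(abs(rowMeans(sums))), 1e-10)
})

test_that("seasonal windows attribute December to the following winter", {
  g <- tinyGrid()
  times <- seq(as.Date("2000-01-01"), by = "month", length.out = 36)
  vals <- array(0, c(36, 3, 4))
  vals[times == as.Date("2000-12-01"), , ] <- 2.5  # only Dec 2000 nonzero
  stk <- monthlyFieldStack("T2M", vals, times, g, "degC")
  expect_equal(seasonalWindowMean(stk, "DecApr", 2001),
               matrix(2.5 / 5, 3, 4), tolerance = 1e-12)
  expect_equal(max(abs(seasonalWindowMean(stk, "MaySep", 2001))), 0)

  rnd <- randomMonthlyStack("T2M", nMonths = 36, seed = 14, units = "degC")
  w <- seasonalWindowMean(rnd, "MaySep", 2001)
  r <- which(rnd@times %in% as.Date(sprintf("2001-%02d-01", 5:9)))
  for (i in 1:3) for (j in 1:4)
    expect_equal(w[i, j], mean(rnd@values[r, i, j]), tolerance = 1e-12)
  expect_error(seasonalWindowMean(rnd, "DecApr", 2000), "incomplete window")
})

test_that("annual and seasonal integrations are linear operators", {
  x <- randomMonthlyStack("NBP", nMonths = 24, seed = 15)
  y <- randomMonthlyStack("NBP", nMonths = 24, seed = 16)
  comb <- monthlyFieldStack("NBP", 2 * x@values - 3 * y@values, x@times, x@grid)
  expect_equal(annualIntegral(comb, 2001),
               2 * annualIntegral(x, 2001) - 3 * annualIntegral(y, 2001),
               tolerance = 1e-10)
  expect_equal(seasonalWindowMean(comb, "MaySep", 2001),
               2 * seasonalWindowMean(x, "MaySep", 2001) -
                 3 * seasonalWindowMean(y, "MaySep", 2001),
               tolerance = 1e-10)
})

test_that("regional integration matches a brute-force loop with spherical cell areas", {
  g <- gridSpec(seq(40, 46, 2), seq(0, 8, 2))  # 4 x 5
  box <- regionBox("b", 1, 7.3, 40.6, 45.1)
  mask <- buildRegionMask(box, g)
  set.seed(17)
  f <- matrix(rnorm(20), 4, 5)
  areas <- cellAreas(g)
  accI <- 0; accW <- 0
  for (i in 1:4) for (j in 1:5) {
    accI <- accI + f[i, j] * areas[i, j] * mask@weights[i, j]
    accW <- accW + areas[i, j] * mask@weights[i, j]
  }
  expect_equal(regionalIntegrate(f, mask, "integral"), accI, tolerance = 1e-12)
  expect_equal(regionalIntegrate(f, mask, "mean"), accI / accW, tolerance = 1e-12)

  # uniform intensive field -> mean c; single-cell mask -> value x area
  expect_equal(regionalIntegrate(matrix(4.2, 4, 5), mask, "mean"), 4.2,
               tolerance = 1e-12)
  one <- new("RegionMask", grid = g, name = "one",
             weights = matrix(c(1, rep(0, 19)), 4, 5))
  expect_equal(regionalIntegrate(f, one, "integral"), f[1, 1] * areas[1, 1],
               tolerance = 1e-12)
  empty <- new("RegionMask", grid = g, name = "none", weights = matrix(0, 4, 5))
  expect_error(regionalIntegrate(f, empty), "empty region")
})

test_that("regional integrals over a partition sum to the full-domain integral", {
  g <- gridSpec(seq(40, 46, 2), seq(0, 8, 2))
  left <- buildRegionMask(regionBox("l", -1, 4, 39, 47), g)
  right <- buildRegionMask(regionBox("r", 4, 9, 39, 47), g)
  whole <- buildRegionMask(regionBox("w", -1, 9, 39, 47), g)
  set.seed(18)
  for (rep in 1:10) {
    f <- matrix(rnorm(20), 4, 5)
    s <- regionalIntegrate(f, left, "integral") + regionalIntegrate(f, right, "integral")
    w <- regionalIntegrate(f, whole, "integral")
    expect_lt(abs(s - w) / max(abs(w), 1e-12), 1e-10)
  }
})

test_that("NDVI annual integrals and anomalies follow the departure definition", {
  g <- tinyGrid(2, 2)
  nY <- 5
  # identical years -> zero anomalies
  one <- array(rep(0.4, 24 * nY * 4), c(24 * nY, 2, 2))
  same <- biweeklyFieldStack(one, 2001:2005, g)
  expect_equal(max(abs(integrateNdviAnnual(same)$anomalies)), 0, tolerance = 1e-12)

  # one year +delta per sample -> anomaly 24 delta (1 - 1/n)
  delta <- 0.01
  pert <- one
  pert[1:24, , ] <- 0.4 + delta
  res <- integrateNdviAnnual(biweeklyFieldStack(pert, 2001:2005, g))
  expect_equal(res$anomalies[1, 1, 1], 24 * delta * (1 - 1 / nY), tolerance = 1e-10)
  expect_equal(res$anomalies[2, 1, 1], -24 * delta / nY, tolerance = 1e-10)

  # random stack: integrals equal naive 24-term sums
  set.seed(19)
  rnd <- array(runif(24 * nY * 4, -0.5, 0.9), c(24 * nY, 2, 2))
  stk <- biweeklyFieldStack(rnd, 2001:2005, g)
  out <- integrateNdviAnnual(stk)
  yy <- as.integer(format(stk@times, "%Y"))
  integ <- sapply(2001:2005, function(y) sum(rnd[yy == y, 1, 2]))
  expect_equal(out$anomalies[, 1, 2], integ - mean(integ), tolerance = 1e-10)
})

test_that("PDSI departures centre the regional mean series", {
  g <- tinyGrid()
  times <- seq(as.Date("2000-01-01"), by = "month", length.out = 24)
  mask <- buildRegionMask(regionBox("b", -1, 7, 39, 45), g)
  cst <- monthlyFieldStack("PDSI", array(2, c(24, 3, 4)), times, g, "1")
  expect_equal(max(abs(pdsiRegionalDeparture(cst, mask)$values)), 0,
               tolerance = 1e-12)
  set.seed(20)
  p <- rnorm(24)
  uni <- monthlyFieldStack("PDSI", array(rep(p, 12), c(24, 3, 4)), times, g, "1")
  expect_equal(pdsiRegionalDeparture(uni, mask)$values, p - mean(p),
               tolerance = 1e-10)
  rnd <- randomMonthlyStack("PDSI", nMonths = 24, seed = 21, units = "1")
  dep <- pdsiRegionalDeparture(rnd, mask)$values
  oracle <- vapply(1:24, function(t) regionalIntegrate(rnd@values[t, , ], mask, "mean"), 0)
  expect_equal(dep, oracle - mean(oracle), tolerance = 1e-12)
})
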