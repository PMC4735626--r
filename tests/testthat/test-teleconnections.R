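test_that("winter DJF means follow the January-year labelling and masked-month rule", {
  times <- seq(as.Date("1981-01-01"), as.Date("1983-12-01"), by = "month")
  v <- rep(0, length(times))
  v[times == as.Date("1981-12-01")] <- 1
  v[times == as.Date("1982-01-01")] <- 1
  v[times == as.Date("1982-02-01")] <- 1
  s <- teleconnectionSeries("NAO", times, v)
  w <- winterIndex(s)
  expect_equal(w@values[w@winterYears == 1982], 1)

  # masked December: mean of the two remaining months
  v2 <- v
  v2[times == as.Date("1981-12-01")] <- NA
  v2[times == as.Date("1982-01-01")] <- 0.2
  v2[times == as.Date("1982-02-01")] <- 0.4
  w2 <- winterIndex(teleconnectionSeries("NAO", times, v2))
  expect_equal(w2@values[w2@winterYears == 1982], 0.3)

  # a single unmasked month is not enough
  v3 <- v2
  v3[times == as.Date("1982-01-01")] <- NA
  w3 <- winterIndex(teleconnectionSeries("NAO", times, v3))
  expect_true(is.na(w3@values[w3@winterYears == 1982]))
})

test_that("winter means equal an explicit 3-month block-mean loop over 31 winters", {
  times <- seq(as.Date("1981-12-01"), as.Date("2012-02-01"), by = "month")
  set.seed(11)
  v <- rnorm(length(times))
  w <- winterIndex(teleconnectionSeries("NAO", times, v))
  expect_identical(w@winterYears, 1982:2012)
  for (y in 1982:2012) {
    idx <- which(times %in% as.Date(sprintf("%d-%02d-01",
                                            c(y - 1, y, y), c(12, 1, 2))))
    expect_equal(w@values[w@winterYears == y], mean(v[idx]), tolerance = 1e-12)
  }
})

test_that("tercile classification matches a sort-and-count oracle and the joint rule", {
  set.seed(21)
  n <- 300
  years <- 1701:2000
  nao <- new("WinterIndexSeries", name = "NAO", winterYears = years, values = rnorm(n))
  ea <- new("WinterIndexSeries", name = "EA", winterYears = years, values = rnorm(n))
  a <- classifyPhases(nao, ea)

  for (ix in c("nao", "ea")) {
    v <- slot(a, ix)
    lower <- oracleTercile(v, 1 / 3)
    upper <- oracleTercile(v, 2 / 3)
    ph <- slot(a, paste0(ix, "Phase"))
    expect_identical(ph, ifelse(v > upper, "+", ifelse(v < lower, "-", "0")))
    # each single-index phase holds 100 +- rounding members
    expect_lte(abs(sum(ph == "+") - 100), 1)
    expect_lte(abs(sum(ph == "-") - 100), 1)
  }
  # joint composite frequencies equal the brute-force cross-count
  brute <- table(paste(a@naoPhase, a@eaPhase))
  expect_identical(sum(a@composite == "N+E+"), unname(brute[["+ +"]]))
  expect_identical(sum(a@composite == "N-E-"), unname(brute[["- -"]]))
  expect_identical(sum(a@composite == "N+E-"), unname(brute[["+ -"]]))
  expect_identical(sum(a@composite == "N-E+"), unname(brute[["- +"]]))
  # composite non-neutral iff both phases non-zero
  expect_identical(a@composite %in% c("N+E+", "N-E-", "N+E-", "N-E+"),
                   a@naoPhase != "0" & a@eaPhase != "0")
})

test_that("phase classification is invariant under strictly monotone transforms", {
  set.seed(22)
  years <- 1901:1960
  vn <- rnorm(60); ve <- rnorm(60)
  mk <- function(nm, v) new("WinterIndexSeries", name = nm,
                            winterYears = years, values = v)
  a1 <- classifyPhases(mk("NAO", vn), mk("EA", ve))
  a2 <- classifyPhases(mk("NAO", exp(2 * vn)), mk("EA", atan(ve) * 5 + 1))
  expect_identical(a1@composite, a2@composite)
})

test_that("classification needs at least 9 base winters", {
  years <- 2001:2008
  mk <- function(nm) new("WinterIndexSeries", name = nm,
                         winterYears = years, values = rnorm(8))
  expect_error(classifyPhases(mk("NAO"), mk("EA")), "too short for terciles")
})

test_that("composite membership partitions the winters", {
  a <- makeAssignment(2000:2002, c("N-E-", "neutral", "N+E-"))
  m <- compositeMembership(a)
  expect_identical(vapply(m, length, 1L),
                   c("N+E+" = 0L, "N-E-" = 1L, "N+E-" = 1L, "N-E+" = 0L,
                     "neutral" = 1L))
  set.seed(30)
  for (rep in 1:20) {
    yrs <- 1980 + seq_len(sample(10:40, 1))
    comp <- sample(compositeLabels(), length(yrs), replace = TRUE)
    mm <- compositeMembership(makeAssignment(yrs, comp))
    expect_setequal(unlist(mm, use.names = FALSE), yrs)
    allPairs <- utils::combn(names(mm), 2)
    for (j in seq_len(ncol(allPairs)))
      expect_length(intersect(mm[[allPairs[1, j]]], mm[[allPairs[2, j]]]), 0)
  }
})

test_that("longest anti-phase run matches a brute-force scan", {
  a <- makeAssignment(2000:2002, c("N+E-", "N-E+", "neutral"))
  r <- longestAntiphaseRun(a)
  expect_identical(r, list(startYear = 2000L, length = 2L))

  bruteRun <- function(yrs, comp) {
    anti <- comp %in% c("N+E-", "N-E+")
    best <- list(startYear = NA_integer_, length = 0L)
    for (i in seq_along(yrs)) for (j in i:length(yrs)) {
      span <- i:j
      if (all(anti[span]) && all(diff(yrs[span]) == 1) &&
          (j - i + 1L) > best$length)
        best <- list(startYear = yrs[i], length = j - i + 1L)
    }
    best
  }
  set.seed(31)
  for (rep in 1:20) {
    yrs <- 1950L + seq_len(sample(5:35, 1))
    comp <- sample(compositeLabels(), length(yrs), replace = TRUE,
                   prob = c(1, 1, 2, 2, 2))
    a2 <- makeAssignment(yrs, comp)
    expect_identical(longestAntiphaseRun(a2), bruteRun(yrs, comp))
  }
})

test_that("varimax rotation matches a brute-force planar angle scan", {
  set.seed(41)
  thetas <- seq(0, 90, by = 0.1) * pi / 180
  for (rep in 1:10) {
    L <- matrix(rnorm(60), 30, 2) %*% diag(c(2, 1))
    vm <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
    crits <- vapply(thetas, function(th) varimaxCriterion(L %*% rot2(th)), 0)
    bestTheta <- thetas[which.max(crits)] * 180 / pi
    R <- vm$rotmat
    got <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    d <- abs(got - bestTheta) %% 90
    expect_lt(min(d, 90 - d), 0.5)
  }
})

test_that("a rank-1 stack yields one mode explaining all variance", {
  g <- gridSpec(seq(30, 70, 4), seq(-80, 40, 4))
  p <- outer(sin(g@lat / 10), cos(g@lon / 20))
  times <- seq(as.Date("1990-01-01"), by = "month", length.out = 180)
  set.seed(5)
  a <- rnorm(180)
  vals <- array(0, c(180, length(g@lat), length(g@lon)))
  for (t in 1:180) vals[t, , ] <- a[t] * p
  stk <- monthlyFieldStack("Z500", vals, times, g, "gpm")
  dom <- regionBox("d", -90, 50, 20, 80)
  ms <- computeRotatedModes(stk, dom, months = 1:12, nRetain = 1)
  expect_equal(ms@explainedVariance, 1, tolerance = 1e-8)
  expect_gt(abs(patternCongruence(ms@loadings[1, , ], p)), 0.999)
  expect_error(computeRotatedModes(stk, dom, months = 1:12, nRetain = 5),
               "exceeds")
})

test_that("rotated modes recover the injected dipoles with uncorrelated amplitudes", {
  cfg <- syntheticConfig(seed = 7)
  idx <- simulateModeIndices(cfg)
  z <- simulateZ500Stack(cfg, idx)
  pats <- truthModePatterns(cfg)
  w <- areaWeights(pats$grid)
  dom <- regionBox("na", -90, 50, 20, 80)
  ms <- computeRotatedModes(z, dom, nRetain = 2,
                            references = list(pats$nao, pats$ea))
  expect_gt(abs(patternCongruence(ms@loadings[1, , ], pats$nao, w)), 0.95)
  expect_gt(abs(patternCongruence(ms@loadings[2, , ], pats$ea, w)), 0.95)
  expect_lt(abs(stats::cor(ms@amplitudes)[1, 2]), 0.1)
  # varimax preserves the total retained variance
  un <- computeRotatedModes(z, dom, nRetain = 2, rotate = FALSE)
  expect_equal(sum(ms@explainedVariance), sum(un@explainedVariance),
               tolerance = 1e-10)
  expect_lte(sum(un@explainedVariance), 1)
  # positive amplitude correlates positively with the truth (NAO sign fix)
  djf <- as.integer(format(idx$truth$times, "%m")) %in% c(12, 1, 2)
  expect_gt(stats::cor(ms@amplitudes[, 1], idx$truth$amplitudes[djf, "NAO"]), 0.9)
})

test_that("recovered amplitudes keep the injected AR(1) autocorrelation", {
  cfg <- syntheticConfig(nYears = 42, seed = 13)   # > 500 analysed months
  idx <- simulateModeIndices(cfg)
  z <- simulateZ500Stack(cfg, idx)
  pats <- truthModePatterns(cfg)
  dom <- regionBox("na", -90, 50, 20, 80)
  ms <- computeRotatedModes(z, dom, months = 1:12, nRetain = 2,
                            references = list(pats$nao, pats$ea))
  for (m in 1:2) {
    a <- ms@amplitudes[, m]
    lag1 <- stats::cor(a[-1], a[-length(a)])
    expect_lt(abs(lag1 - cfg$rho), 0.1)
  }
})
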