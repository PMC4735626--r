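# shared fixture builders; everything is generated in code

tinyGrid <- function(nlat = 3, nlon = 4, lat0 = 40, lon0 = 0, dlat = 2, dlon = 2) {
  gridSpec(seq(lat0, by = dlat, length.out = nlat),
           seq(lon0, by = dlon, length.out = nlon))
}

randomMonthlyStack <- function(variable = "NBP", nMonths = 24, grid = tinyGrid(),
                               start = "2000-01-01", seed = 1, units = "gC m-2 month-1",
                               maskFrac = 0) {
  set.seed(seed)
  nlat <- length(grid@lat); nlon <- length(grid@lon)
  v <- array(rnorm(nMonths * nlat * nlon), c(nMonths, nlat, nlon))
  if (maskFrac > 0) v[sample(length(v), round(maskFrac * length(v)))] <- NA
  monthlyFieldStack(variable, v, seq(as.Date(start), by = "month", length.out = nMonths),
                    grid, units)
}

# direct PhaseAssignment builder for partition/run tests
makeAssignment <- function(years, composite) {
  phase <- list("N+E+" = c("+", "+"), "N-E-" = c("-", "-"), "N+E-" = c("+", "-"),
                "N-E+" = c("-", "+"), "neutral" = c("0", "0"))
  ph <- t(vapply(composite, function(cc) phase[[cc]], c("", "")))
  new("PhaseAssignment", winterYears = as.integer(years),
      nao = rep(0, length(years)), ea = rep(0, length(years)),
      naoPhase = ph[, 1], eaPhase = ph[, 2], composite = composite,
      thresholds = c(nao.lower = -0.5, nao.upper = 0.5,
                     ea.lower = -0.5, ea.upper = 0.5))
}

# independent type-7 tercile computation (sort + linear interpolation of
# order statistics), used as oracle against classifyPhases
oracleTercile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# raw varimax simplicity criterion for a 2-column loading matrix
varimaxCriterion <- function(L) {
  sum(apply(L^2, 2, function(z) mean(z^2) - mean(z)^2))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
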