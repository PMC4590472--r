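test_that("trend fit recovers exact lines and rejects constants", {
  s <- monthlySeries(2 * (0:35) + 1)
  tr <- suppressWarnings(fitTrend(s))  # exact fit
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 1)
  expect_equal(tr$pctVar, 100)
  expect_true(tr$retained)

  const <- suppressWarnings(fitTrend(monthlySeries(rep(3, 36))))
  expect_false(const$retained)
  expect_equal(const$slope, 0)
  expect_error(fitTrend(monthlySeries(rep(NA_real_, 36))), "missing")
})

test_that("trend recovery stays inside 2 s.e. at the decadal slope scale", {
  # slope of the decadal LNA-abundance trend, 0.016 per year
  set.seed(31)
  seeds <- sample.int(1e6, 200)
  hits <- vapply(seeds, function(sd) {
    s <- generateSeries(120, mean = 5.47, trendSlope = 0.016 / 12,
                        noiseSd = 0.2256, seed = sd)
    tr <- fitTrend(s)
    se <- summary(stats::lm(seriesValues(s) ~ monthIndex(s)))$
      coefficients["monthIndex(s)", "Std. Error"]
    abs(tr$slope - 0.016 / 12) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("periodogram concentrates a pure Fourier cosine in one ordinate", {
  s <- generateSeries(120, harmonics = list(list(period = 12,
                                                 amplitude = 1,
                                                 phase = 0.7)))
  pg <- periodogram(s)
  expect_equal(attr(pg, "method"), "classical")
  expect_equal(pg$period[which.max(pg$ordinate)], 12)
  expect_gt(max(pg$ordinate) / sum(pg$ordinate), 0.999999)
})

test_that("periodogram satisfies the Parseval identity", {
  set.seed(33)
  x <- rnorm(121)  # odd length: no Nyquist ordinate
  pg <- periodogram(x)
  xc <- x - mean(x)
  expect_equal(2 * sum(pg$ordinate), sum(xc^2), tolerance = 1e-10)
  expect_error(periodogram(rnorm(5)), "at least 8")
})

test_that("gappy series fall back to Lomb-Scargle and find the peak", {
  s <- generateSeries(120, harmonics = list(list(period = 12,
                                                 amplitude = 2,
                                                 phase = 1)),
                      noiseSd = 0.5, missingFraction = 0.2, seed = 34)
  pg <- periodogram(s)
  expect_equal(attr(pg, "method"), "lomb-scargle")
  expect_equal(pg$period[which.max(pg$ordinate)], 12)
})

test_that("Fisher G-test matches its exact null distribution", {
  # the p-value at the observed g equals the closed-form series; compare
  # against a direct high-precision evaluation at small m
  m <- 10
  gVals <- c(0.12, 0.2, 0.35, 0.6, 0.9)
  for (g in gVals) {
    j <- seq_len(floor(1 / g))
    j <- j[j <= m]
    direct <- sum((-1)^(j - 1) * choose(m, j) * (1 - j * g)^(m - 1))
    got <- fisherGTest(c(g, rep((1 - g) / (m - 1), m - 1)))
    expect_equal(got$p, min(max(direct, 0), 1), tolerance = 1e-12)
    expect_equal(got$g, g, tolerance = 1e-12)
  }
  expect_error(fisherGTest(rep(0, 10)), "zero-variance")
  expect_error(fisherGTest(c(1, 2, 3)), "at least 4")
})

test_that("a dominant ordinate drives the G-test p-value towards zero", {
  p <- fisherGTest(c(1000, rep(1e-6, 59)))$p
  expect_lt(p, 1e-30)
})

test_that("white-noise G-test rejections stay near the nominal rate", {
  set.seed(35)
  reject <- vapply(1:300, function(i) {
    fisherGTest(periodogram(rnorm(120)))$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})

test_that("noiseless harmonics are recovered to machine precision", {
  s <- generateSeries(120, harmonics = list(list(period = 12,
                                                 amplitude = 0.04,
                                                 phase = 2.44)))
  hm <- fitHarmonics(s)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$period, 12, tolerance = 1e-9)
  expect_equal(hm$amplitude, 0.04, tolerance = 1e-9)
  expect_equal(hm$phase, 2.44, tolerance = 1e-9)
  expect_equal(hm$tMax, 2.44 * 12 / (2 * pi), tolerance = 1e-9)
})

test_that("two harmonics are recovered in order of amplitude", {
  s <- generateSeries(120, harmonics = list(
    list(period = 6, amplitude = 1, phase = 0.5),
    list(period = 12, amplitude = 2, phase = 1)))
  hm <- fitHarmonics(s)
  expect_equal(nrow(hm), 2L)
  expect_equal(hm$period, c(12, 6), tolerance = 1e-9)
  expect_equal(hm$amplitude, c(2, 1), tolerance = 1e-9)
  expect_equal(hm$phase, c(1, 0.5), tolerance = 1e-9)
})

test_that("white noise yields an empty harmonic list at about 1 - alpha", {
  set.seed(36)
  empty <- vapply(1:200, function(i) {
    nrow(fitHarmonics(rnorm(120))) == 0L
  }, logical(1))
  expect_gt(mean(empty), 0.90)
})

test_that("phase-to-maximum conversion follows theta * T / 2 pi", {
  expect_equal(tMax(0, 12), 0)
  expect_equal(tMax(pi, 12), 6)
  expect_equal(tMax(4.26, 12), 8.136, tolerance = 1e-3)
})

test_that("the fitted harmonic peaks at tMax months into the cycle", {
  set.seed(37)
  for (i in 1:10) {
    theta <- runif(1, 0, 2 * pi)
    s <- generateSeries(120, harmonics = list(list(period = 12,
                                                   amplitude = 1,
                                                   phase = theta)),
                        noiseSd = 0.3, seed = i)
    hm <- fitHarmonics(s)
    expect_equal(nrow(hm), 1L)
    t <- 0:11
    curve <- hm$amplitude * cos(2 * pi * t / hm$period - hm$phase)
    expect_lte(min(abs(which.max(curve) - 1 - hm$tMax %% 12),
                   12 - abs(which.max(curve) - 1 - hm$tMax %% 12)), 1)
  }
})

test_that("AR identification recovers phi at the study-site persistence", {
  set.seed(38)
  seeds <- sample.int(1e6, 100)
  hits <- vapply(seeds, function(sd) {
    s <- generateSeries(120, arPhi = 0.34, noiseSd = 1, seed = sd)
    ar <- fitAr(seriesValues(s))
    if (nrow(ar) == 0L || ar$lag != 1L) return(NA)
    se <- sqrt((1 - ar$phi^2) / 120)
    abs(ar$phi - 0.34) <= 2.5 * se
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
  expect_lte(mean(is.na(hits)), 0.35)
})

test_that("AR term is absent for white noise and found for strong persistence", {
  set.seed(39)
  absent <- vapply(1:200, function(i) nrow(fitAr(rnorm(120))) == 0L,
                   logical(1))
  expect_gt(mean(absent), 0.85)
  lag1 <- vapply(1:50, function(i) {
    s <- generateSeries(120, arPhi = 0.9, noiseSd = 1, seed = 1000 + i)
    ar <- fitAr(seriesValues(s))
    nrow(ar) == 1L && ar$lag == 1L
  }, logical(1))
  expect_gte(mean(lag1), 0.98)
})

test_that("decomposition ledger sums its parts on every run", {
  set.seed(40)
  for (i in 1:5) {
    s <- generateSeries(120, mean = 10, trendSlope = 0.01,
                        harmonics = list(list(period = 12, amplitude = 1,
                                              phase = 2)),
                        arPhi = 0.3, noiseSd = 0.5, seed = i)
    fit <- decomposeSeries(s)
    parts <- c(trendComponent(fit)$pctVar, harmonics(fit)$pctVar,
               arComponent(fit)$pctVar)
    expect_equal(sum(parts), fit@totalPctVar, tolerance = 1e-12)
    expect_lte(fit@totalPctVar, 100 + 1e-6)
    expect_lt(abs(mean(residuals(fit), na.rm = TRUE)), 0.2)
  }
})

test_that("a biomass-share-like harmonic reports its month of maximum", {
  # mean 44.2, A = 8.40, theta = 5.00 on the annual cycle: maximum at
  # 9.55 months into the cycle
  s <- generateSeries(120, mean = 44.2,
                      harmonics = list(list(period = 12, amplitude = 8.40,
                                            phase = 5.00)),
                      noiseSd = 4, seed = 41)
  fit <- decomposeSeries(s)
  expect_equal(harmonics(fit)$tMax[1], 9.549, tolerance = 0.02)
})

test_that("decomposing residuals again finds nothing (idempotence)", {
  set.seed(42)
  found <- vapply(1:40, function(i) {
    s <- generateSeries(120, mean = 5,
                        harmonics = list(list(period = 12, amplitude = 2,
                                              phase = 1)),
                        noiseSd = 1, seed = 100 + i)
    fit <- decomposeSeries(s)
    r <- monthlySeries(residuals(fit))
    fit2 <- decomposeSeries(r)
    nrow(harmonics(fit2)) + nrow(trendComponent(fit2)) +
      nrow(arComponent(fit2)) > 0
  }, logical(1))
  expect_lte(mean(found), 0.2)
})

test_that("decomposition handles gappy series without fabricating data", {
  s <- generateSeries(120, mean = 15.7,
                      harmonics = list(list(period = 12, amplitude = 3.89,
                                            phase = 4.26)),
                      noiseSd = 1.2, missingFraction = 0.1, seed = 43)
  fit <- decomposeSeries(s)
  expect_equal(nrow(harmonics(fit)), 1L)
  expect_equal(harmonics(fit)$amplitude[1], 3.89, tolerance = 0.15)
  expect_true(all(is.na(residuals(fit)[is.na(seriesValues(s))])))
})
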