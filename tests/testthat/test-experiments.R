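test_that("noiseless size-temperature regressions are exact", {
  temps <- rep(c(12, 15, 18), each = 3)
  rec <- data.frame(month = 5, group = "LNA", temperature = temps,
                    size = 0.06 - 0.0005 * temps)
  sr <- suppressWarnings(sizeTemperatureSlope(rec))  # exact fit
  expect_equal(sr$slope, -0.0005)
  expect_equal(sr$intercept, 0.06)
  expect_equal(sr$r2, 1)
  flat <- data.frame(temperature = temps, size = rep(0.05, 9))
  expect_equal(suppressWarnings(sizeTemperatureSlope(flat))$slope, 0)
  expect_error(sizeTemperatureSlope(rec[1:2, ]), "at least 3")
  expect_error(sizeTemperatureSlope(
    data.frame(temperature = rep(15, 5), size = rnorm(5, 0.05, 0.001))),
    "temperature level")
})

test_that("slope is shift-invariant in size and scales linearly", {
  set.seed(60)
  rec <- generateExperiment(seed = 61)
  lna <- rec[rec$group == "LNA", ]
  s1 <- sizeTemperatureSlope(lna)$slope
  shifted <- lna; shifted$size <- shifted$size + 0.1
  expect_equal(sizeTemperatureSlope(shifted)$slope, s1)
  scaled <- lna; scaled$size <- scaled$size * 3
  expect_equal(sizeTemperatureSlope(scaled)$slope, 3 * s1)
})

test_that("generated group responses are recovered within 2 s.e.", {
  set.seed(62)
  hits <- vapply(1:100, function(i) {
    ex <- generateExperiment(seed = 6200 + i)
    lna <- sizeTemperatureSlope(ex[ex$group == "LNA", ])
    hna <- sizeTemperatureSlope(ex[ex$group == "HNA", ])
    abs(lna$slope + 0.00041) <= 2 * lna$slopeSe &&
      abs(hna$slope + 0.00091) <= 2 * hna$slopeSe
  }, logical(1))
  # each group's 2 s.e. interval covers with P(|t_7| <= 2) = 0.915, so
  # the joint event runs near 0.84
  expect_gte(mean(hits), 0.75)
})

test_that("cross-group regression ties the two groups' responses", {
  lna <- data.frame(month = 1:12, slope = seq(-0.001, 0.0002,
                                              length.out = 12))
  ident <- suppressWarnings(crossGroupSlopeRegression(lna, lna))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r2, 1)
  expect_error(crossGroupSlopeRegression(lna[1:2, ], lna[1:2, ]),
               "matched months")

  # HNA responds 1.19 times as strongly as LNA, as in the incubations
  set.seed(63)
  hits <- vapply(1:100, function(i) {
    lnaS <- data.frame(month = 1:12, slope = rnorm(12, -4e-4, 6e-4))
    hnaS <- data.frame(month = 1:12,
                       slope = -2e-4 + 1.19 * lnaS$slope +
                         rnorm(12, 0, 4e-4))
    cg <- crossGroupSlopeRegression(lnaS, hnaS)
    abs(cg$slope - 1.19) <= 2 * cg$slopeSe
  }, logical(1))
  expect_gte(mean(hits), 0.88)

  # uncorrelated responses give r2 near zero
  set.seed(64)
  r2s <- vapply(1:50, function(i) {
    crossGroupSlopeRegression(
      data.frame(month = 1:12, slope = rnorm(12)),
      data.frame(month = 1:12, slope = rnorm(12)))$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.25)
})

test_that("window means resolve April-March analysis years", {
  s <- monthlySeries(rep(7, 48), startYear = 2002, startMonth = 4)
  wm <- windowMeanSeries(s, window = 4:7)
  expect_true(all(wm$mean == 7))
  expect_equal(wm$year, 2002:2005)
  # single-month window returns that month's value
  v <- seq_len(48)
  s2 <- monthlySeries(v, startYear = 2002, startMonth = 4)
  wm2 <- windowMeanSeries(s2, window = 5)
  expect_equal(wm2$mean, v[seq(2, 48, by = 12)])
  # December-February window months belong to the year of their April
  s3 <- monthlySeries(v, startYear = 2002, startMonth = 4)
  wm3 <- windowMeanSeries(s3, window = 1)
  expect_equal(wm3$year[1], 2002)  # Jan 2003 sits in analysis year 2002
})

test_that("a linear series returns its generating slope through the window chain", {
  slopePerYear <- 0.15
  s <- generateSeries(120, mean = 14, trendSlope = slopePerYear / 12,
                      startYear = 2002, startMonth = 4)
  tr <- annualTrend(windowMeanSeries(s, window = 4:7))
  expect_equal(tr$slope, slopePerYear, tolerance = 1e-10)
  expect_equal(tr$r2, 1)
  # +0.15 degC/yr over the decade: ~1.5 degC warming
  expect_equal(tr$decadalChange, 1.35, tolerance = 1e-10)  # 9-year span
})

test_that("annual-trend significance holds its size under a zero slope", {
  set.seed(65)
  reject <- vapply(1:500, function(i) {
    am <- data.frame(year = 2002:2011, mean = rnorm(10))
    annualTrend(am)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.075)
})

test_that("decadal warming in the April-July window is detected on synthetic data", {
  set.seed(66)
  s <- generateSeries(120, mean = 15.7, trendSlope = 0.15 / 12,
                      harmonics = list(list(period = 12, amplitude = 3.89,
                                            phase = 4.26)),
                      noiseSd = 0.8, startYear = 2002, startMonth = 4,
                      seed = 67)
  tr <- annualTrend(windowMeanSeries(s, window = 4:7))
  expect_equal(tr$slope * 10, 1.5, tolerance = 0.4)
  expect_lt(tr$p, 0.05)
})

test_that("April-July size cools against temperature on TSR-compliant data", {
  # warming years produce smaller cells: the cross-regression of window
  # means must recover a negative coefficient
  set.seed(68)
  temp <- generateSeries(120, mean = 15.7, trendSlope = 0.15 / 12,
                         harmonics = list(list(period = 12,
                                               amplitude = 3.89,
                                               phase = 4.26)),
                         noiseSd = 0.8, startYear = 2002, startMonth = 4,
                         seed = 69)
  wmT <- windowMeanSeries(temp, window = 4:7)
  sizes <- 0.098 - 0.024 * wmT$mean + rnorm(nrow(wmT), 0, 0.002)
  fit <- stats::lm(sizes ~ wmT$mean)
  expect_lt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, "Pr(>|t|)"], 0.05)
})

test_that("projected size change follows its closed form", {
  expect_equal(projectedSizeChange(c(g = -5e-4), 0, c(g = 0.05),
                                   c(g = 1)), 0)
  expect_equal(projectedSizeChange(c(g = -5e-4), 2, c(g = 0.05),
                                   c(g = 1)), -2)
  # both candidate aggregations of the two-group projection
  slopes <- c(LNA = -0.00041, HNA = -0.00091)
  baselines <- c(LNA = 0.050, HNA = 0.056)
  unweighted <- projectedSizeChange(slopes, 1.5, baselines)
  weighted <- projectedSizeChange(slopes, 1.5, baselines,
                                  c(LNA = 0.46, HNA = 0.54))
  expect_lt(unweighted, 0)
  expect_lt(weighted, 0)
  expect_equal(unweighted,
               100 * mean(slopes * 1.5 / baselines), tolerance = 1e-12)
  expect_error(projectedSizeChange(slopes, 1.5, c(LNA = 0, HNA = 0.056)),
               "positive")
  expect_error(projectedSizeChange(slopes, 1.5, baselines,
                                   c(LNA = 0.3, HNA = 0.3)), "sum to 1")
})
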