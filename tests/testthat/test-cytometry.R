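test_that("well-separated clouds are gated to their true groups", {
  ev <- generateCytogram(500, lnaCenter = c(10, 8), hnaCenter = c(40, 12),
                         clusterSd = 0.08, seed = 5)
  labels <- gateLnaHna(ev)
  agreement <- mean(as.character(labels) == ev$trueGroup)
  expect_gte(agreement, 0.99)
  expect_false(attr(labels, "singleCluster"))
})

test_that("fully overlapping clouds gate at chance level", {
  # identical centers except the infinitesimal green offset the generator
  # requires: labels carry no information, agreement ~ 50%
  ev <- generateCytogram(2000, lnaCenter = c(20, 10),
                         hnaCenter = c(20.0001, 10), clusterSd = 0.1,
                         seed = 6)
  agreement <- mean(as.character(gateLnaHna(ev)) == ev$trueGroup)
  expect_gt(agreement, 0.4)
  expect_lt(agreement, 0.6)
})

test_that("degenerate identical events are flagged as a single cluster", {
  ev <- data.frame(green = rep(10, 100), rals = rep(5, 100),
                   red = rep(1, 100))
  labels <- gateLnaHna(ev)
  expect_true(attr(labels, "singleCluster"))
  expect_equal(length(unique(stats::na.omit(as.character(labels)))), 1L)
})

test_that("high-red photosynthetic events are excluded before gating", {
  ev <- generateCytogram(300, nRedEvents = 50, seed = 7)
  labels <- gateLnaHna(ev, redThreshold = 100)
  expect_true(all(is.na(labels[ev$trueGroup == "photosynthetic"])))
  expect_true(all(!is.na(labels[ev$trueGroup != "photosynthetic"])))
})

test_that("a generated LNA/HNA mix is recovered within two points", {
  # 45/55 mix near the observed HNA share of the study site
  ev <- rbind(generateCytogram(900, seed = 8)[1:900, ],        # LNA
              generateCytogram(1100, seed = 9)[1101:2200, ])   # HNA
  attr(ev, "flowRate") <- 60; attr(ev, "acquisitionTime") <- 60
  labels <- gateLnaHna(ev)
  hnaFrac <- mean(labels == "HNA", na.rm = TRUE)
  expect_equal(hnaFrac, 0.55, tolerance = 0.02 / 0.55)
})

test_that("abundance converts counts through the analysed volume", {
  # 1000 events in 1 ul -> 1e6 cells/ml
  ev <- data.frame(green = rep(c(5, 50), 500), rals = rep(10, 1000),
                   red = rep(1, 1000))
  attr(ev, "flowRate") <- 1; attr(ev, "acquisitionTime") <- 60
  labels <- gateLnaHna(ev)
  ab <- cytometryAbundance(ev, labels)
  expect_equal(unname(ab["total"]), 1e6)
  expect_equal(unname(ab["LNA"] + ab["HNA"]), unname(ab["total"]))
  # empty group -> 0
  labAllHna <- factor(rep("HNA", 1000), levels = c("LNA", "HNA"))
  expect_equal(unname(cytometryAbundance(ev, labAllHna)["LNA"]), 0)
  expect_error(cytometryAbundance(ev, labels, flowRate = 0), "positive")
})

test_that("counting recovers a generated concentration within Poisson error", {
  # 5e5 cells/ml analysed over 0.06 ml -> expect 30000 counted cells;
  # generator draws the exact event count, so recovery is exact here and
  # the Poisson band is the tolerance a real sample would need
  target <- 5e5
  volumeMl <- 60 * 60 / 60 / 1000
  nEvents <- round(target * volumeMl / 2)
  ev <- generateCytogram(nEvents, seed = 10)
  ab <- cytometryAbundance(ev, gateLnaHna(ev))
  expect_equal(unname(ab["total"]), target,
               tolerance = 3 * sqrt(2 * nEvents) / (2 * nEvents))
})

test_that("scatter-to-volume conversion assumes spherical cells", {
  cal05 <- sizeCalibration(logIntercept = log10(0.5) - 0.25,
                           logSlope = 0.25)
  expect_equal(ralsToVolume(10, cal05), pi / 6 * 0.125,
               tolerance = 1e-10)  # d = 0.5 um -> 0.0654 um3
  cal1 <- sizeCalibration(logIntercept = -0.25, logSlope = 0.25)
  expect_equal(ralsToVolume(10, cal1), pi / 6, tolerance = 1e-10)
  # monotone: higher RALS, larger volume
  v <- ralsToVolume(c(5, 10, 20, 40), cal05)
  expect_true(all(diff(v) > 0))
  expect_warning(ralsToVolume(1e5, cal05), "extrapolat")
})

test_that("allometric carbon conversion matches its closed form", {
  expect_equal(biomassPerCell(1), 0.12)
  expect_equal(biomassPerCell(0.05), 0.12 * 0.05^0.72)  # 0.01388
  expect_equal(biomassPerCell(2) / biomassPerCell(1), 2^0.72)
  expect_error(biomassPerCell(0), "positive")
})

test_that("biomass concentration is linear in abundance and monotone in volume", {
  expect_equal(biomassConcentration(1e6, 1), 120)
  expect_equal(biomassConcentration(0, 1), 0)
  expect_equal(biomassConcentration(2e5, 0.05),
               2 * biomassConcentration(1e5, 0.05))
  expect_lt(biomassConcentration(1e5, 0.04),
            biomassConcentration(1e5, 0.06))
})

test_that("capped-cylinder biovolume reduces to the sphere for cocci", {
  d <- 0.7
  expect_equal(biovolumeFromDimensions(d, d), pi / 6 * d^3)
  expect_equal(biovolumeFromDimensions(1, 0.5),
               pi / 4 * 0.25 * (1 - 0.5 / 3))  # 0.1636
  ls <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(biovolumeFromDimensions(ls, 0.5)) > 0))
  expect_error(biovolumeFromDimensions(0.4, 0.5), "exceed")
})

test_that("population stats satisfy the group identities", {
  ev <- generateCytogram(800, seed = 12)
  ps <- populationStats(ev)
  lna <- ps[ps$group == "LNA", ]; hna <- ps[ps$group == "HNA", ]
  tot <- ps[ps$group == "total", ]
  expect_equal(tot$abundance, lna$abundance + hna$abundance)
  # total mean size = abundance-weighted mean of group sizes
  expect_equal(tot$size,
               (lna$abundance * lna$size + hna$abundance * hna$size) /
                 tot$abundance)
  expect_true(all(ps$size > 0.01 & ps$size < 0.5))
  expect_equal(tot$biomass,
               biomassConcentration(tot$abundance, tot$size))
})
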