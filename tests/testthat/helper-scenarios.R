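# Shared scenario builders for the test suite. All randomness is seeded
# at the call site so every test is reproducible in isolation.

# The annual temperature cycle of the monitored site: mean 15.7 degC,
# amplitude 3.89, phase 4.26 rad, lag-1 autocorrelation 0.34; innovation
# sd 1.276 puts ~80% of total variance in the harmonic and ~2% in the AR
# term.
tempScenario <- function(seed, nMonths = 120L) {
  generateScenarioSeries("temperature", nMonths = nMonths, seed = seed)
}

# Pure annual harmonic plus white noise at a chosen periodic-variance
# share (0 < share < 1): sigma^2 = (A^2/2) * (1 - share) / share.
harmonicWithNoise <- function(seed, amplitude = 3.89, phase = 4.26,
                              share = 0.8, nMonths = 120L) {
  sdNoise <- sqrt((amplitude^2 / 2) * (1 - share) / share)
  generateSeries(nMonths, mean = 0,
                 harmonics = list(list(period = 12, amplitude = amplitude,
                                       phase = phase)),
                 noiseSd = sdNoise, seed = seed)
}

# Independent-oracle grid search for a single harmonic on a noiseless
# series: hierarchical refinement of a dense (T, A, theta) grid by
# minimising the sum of squared errors directly. Never calls the
# package's fitting path.
gridSearchHarmonic <- function(x, tGrid = NULL, rounds = 12L) {
  t <- seq_along(x) - 1
  n <- length(x)
  Amax <- 2 * max(abs(x))
  lims <- list(T = c(2, n / 2), A = c(0, Amax), th = c(0, 2 * pi))
  best <- c(T = 12, A = Amax / 2, th = pi)
  width <- c(T = diff(lims$T), A = diff(lims$A), th = diff(lims$th))
  for (r in seq_len(rounds)) {
    Ts <- seq(max(lims$T[1], best["T"] - width["T"] / 2),
              min(lims$T[2], best["T"] + width["T"] / 2), length.out = 25)
    As <- seq(max(0, best["A"] - width["A"] / 2),
              best["A"] + width["A"] / 2, length.out = 25)
    ths <- seq(best["th"] - width["th"] / 2,
               best["th"] + width["th"] / 2, length.out = 25)
    grid <- expand.grid(T = Ts, A = As, th = ths)
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum((x - grid$A[i] *
             cos(2 * pi * t / grid$T[i] - grid$th[i]))^2)
    }, numeric(1))
    best <- unlist(grid[which.min(sse), ])
    # shrink slowly: the (T, theta) axes form a coupled valley (changing
    # the period shifts the apparent phase), so aggressive shrinking can
    # strand the box in a side valley
    width <- width / 3
  }
  c(period = unname(best["T"]), amplitude = unname(best["A"]),
    phase = unname(best["th"]) %% (2 * pi))
}
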