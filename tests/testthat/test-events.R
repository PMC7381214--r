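test_that("threshold curves follow their definitions", {
  tr <- processed(rnorm(100), rate = 100)
  expect_equal(makeThreshold(tr, "static", level = 0.02), rep(0.02, 100))

  ## dynamic on constant + white noise approximates mean + k * sigma
  set.seed(51)
  sigma <- 0.3
  tr2 <- processed(2 + rnorm(10000, 0, sigma), rate = 1000)
  th <- makeThreshold(tr2, "dynamic", window = 1, k = 3)
  expect_lt(max(abs(th - (2 + 3 * sigma))) / (3 * sigma), 0.10)

  ## pure slow sine: sigma_noise ~ 0, threshold tracks the sine
  t <- seq(0, 10, length.out = 2000)
  sine <- processed(sin(2 * pi * 0.2 * t), rate = 200)
  ths <- makeThreshold(sine, "dynamic", window = 0.1, k = 3)
  keep <- 100:1900
  expect_lt(max(abs(ths - traceValues(sine))[keep]), 0.05)

  expect_error(makeThreshold(tr, "dynamic", window = 0.01), "3 samples")
  expect_error(makeThreshold(tr, "static"), "level")
})

test_that("spikes are the maxima of supra-threshold runs", {
  v <- rep(0, 100); v[40] <- 5
  tr <- processed(v, rate = 100)
  s <- detectSpikes(tr, makeThreshold(tr, "static", level = 3))
  expect_equal(s@peakIndices, 40L)
  expect_equal(amplitudes(s), 2)

  ## tie rule: two equal peaks 1 sample apart, long refractory
  v2 <- rep(0, 100); v2[50] <- 5; v2[51] <- 5
  tr2 <- processed(v2, rate = 100)
  s2 <- detectSpikes(tr2, rep(3, 100), refractory = 0.1)
  expect_equal(s2@peakIndices, 50L)

  ## an empty SpikeSet is allowed
  s0 <- detectSpikes(tr, rep(10, 100))
  expect_equal(nEvents(s0), 0)
})

test_that("template spikes in noise are found with the dynamic threshold", {
  ## 20 template spikes at 5x the noise SD; the threshold is computed on
  ## the raw trace (its noise-SD estimator assumes white noise) and
  ## detection runs on the Savitzky-Golay-smoothed trace, the workflow
  ## that makes low-SNR spikes detectable
  rate <- 250
  sigma <- 0.01
  spec <- SynthSpec(duration = 20, rate = rate,
                    components = list(spikeComponent(
                      times = seq(0.5, 19.5, length.out = 20),
                      amp = 5 * sigma, shape = "gaussian", width = 0.009)),
                    bleach = c(a = 1, b = 0), noiseSd = sigma, seed = 52)
  out <- synthTrace(spec)
  tr <- processed(traceValues(out$trace) - 1, rate = rate)  # flat baseline
  th <- makeThreshold(tr, "dynamic", window = 1, k = 3)
  sm <- applyFilter(tr, "savitzky_golay", window = 9, polyorder = 2)
  s <- detectSpikes(sm, th, refractory = 0.1)
  truth <- out$truth$spikes$time_s
  ## every spike found within one sample of truth
  matched <- vapply(truth, function(tt) min(abs(peakTimes(s) - tt)), numeric(1))
  expect_true(all(matched <= 1 / rate + 1e-12))
  ## and no detection away from a true spike
  expect_equal(nEvents(s), 20)
  stray <- vapply(peakTimes(s), function(p) min(abs(truth - p)), numeric(1))
  expect_equal(sum(stray > 1 / rate + 1e-12), 0)
})

test_that("detection equals the supra-threshold-run oracle on random traces", {
  set.seed(53)
  for (rep in 1:200) {
    n <- sample(50:200, 1)
    v <- rnorm(n)
    thr <- rep(runif(1, 0, 1.5), n)
    tr <- processed(v, rate = 100)
    s <- detectSpikes(tr, thr)
    expect_identical(s@peakIndices, as.integer(spikeOracle(v, thr)))
  }
})

test_that("burst detection quantifies duration, A_max, t_peak and tau", {
  rate <- 100
  ## square pulse, height 1, width 0.5 s
  v <- rep(0, 300); v[101:150] <- 1
  tr <- processed(v, rate = rate)
  b <- detectBursts(tr, rep(0.5, 300), endFraction = 0.5)
  tb <- burstTable(b)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$duration, 0.5, tolerance = 1 / rate + 1e-12)
  expect_equal(tb$aMax, 1)
  expect_equal(tb$tPeak, 0)  # first maximal sample is the burst start

  ## pulse with exponential tail, b = 2 /s
  t <- (0:999) / rate
  v2 <- numeric(1000)
  on <- t >= 2 & t < 2.2
  v2[on] <- seq(0, 1, length.out = sum(on))
  tail <- t >= 2.2
  v2[tail] <- exp(-2 * (t[tail] - 2.2))
  tr2 <- processed(v2, rate = rate)
  ## small endFraction keeps the tail in the burst, giving the decay fit
  ## enough samples
  b2 <- detectBursts(tr2, rep(0.05, 1000), endFraction = 0.1)
  expect_equal(nrow(burstTable(b2)), 1)
  expect_lt(abs(burstTable(b2)$tauDecay - 0.5) / 0.5, 0.05)

  ## min_duration filters the short pulse
  v3 <- numeric(400); v3[101:140] <- 1; v3[301:305] <- 1
  tr3 <- processed(v3, rate = rate)
  b3 <- detectBursts(tr3, rep(0.5, 400), minDuration = 0.2)
  expect_equal(nrow(burstTable(b3)), 1)

  ## A_max and t_peak invariant under additive constants (threshold shifted too)
  shift <- 0.7
  b4 <- detectBursts(processed(v2 + shift, rate = rate),
                     rep(0.05 + shift, 1000), endFraction = 0.1)
  expect_equal(burstTable(b4)$aMax - shift, burstTable(b2)$aMax,
               tolerance = 1e-12)
  expect_equal(burstTable(b4)$tPeak, burstTable(b2)$tPeak)
})

test_that("decay fits recover exponential parameters with tau = 1/b", {
  t <- seq(0, 2, by = 0.01)
  y <- 3 * exp(-2 * t)
  f <- fitDecay(y, 100)
  expect_lt(abs(f@a - 3), 1e-6)
  expect_lt(abs(f@b - 2), 1e-6)
  expect_lt(abs(f@tau - 0.5), 1e-6)
  expect_identical(f@tau, 1 / f@b)  # defining identity, bit-exact

  ## noisy recovery: median over 100 replicates within 5%
  set.seed(54)
  taus <- replicate(100, {
    fn <- fitDecay(y + rnorm(length(y), 0, 0.05), 100)
    expect_identical(fn@tau, 1 / fn@b)
    fn@tau
  })
  expect_lt(abs(median(taus) - 0.5) / 0.5, 0.05)

  expect_error(fitDecay(-y, 100), "positive first sample")
  expect_error(fitDecay(y[1:3], 100), "4 samples")
})

test_that("event shapes average aligned windows", {
  rate <- 100
  tri <- c(seq(0, 1, length.out = 6), seq(0.8, 0, length.out = 5))  # 11 samples
  v <- numeric(1000)
  peaks <- c(100, 250, 400, 550, 700)
  for (p in peaks) v[(p - 5):(p + 5)] <- tri
  tr <- processed(v, rate = rate)
  sset <- new("SpikeSet", peakTimes = (peaks - 1) / rate,
              peakIndices = as.integer(peaks),
              amplitudes = rep(1, 5), tauDecay = rep(NA_real_, 5),
              threshold = rep(0, 1000), rate = rate, duration = 10)
  es <- eventShape(tr, sset, pre = 0.05, post = 0.05)
  expect_equal(es@waveform, tri, tolerance = 1e-12)
  expect_true(all(es@sd == 0))
  expect_equal(es@nEvents, 5L)

  ## event too close to the edge is excluded (and counted)
  sset2 <- new("SpikeSet", peakTimes = c(0.01, (peaks - 1) / rate),
               peakIndices = as.integer(c(2, peaks)),
               amplitudes = rep(1, 6), tauDecay = rep(NA_real_, 6),
               threshold = rep(0, 1000), rate = rate, duration = 10)
  es2 <- eventShape(tr, sset2, pre = 0.5, post = 0.05)
  expect_equal(es2@nExcluded, 1L)

  ## averaging suppresses noise like 1/sqrt(n): long windows (101 samples)
  ## averaged over replicate traces keep the SD estimates tight
  set.seed(55)
  template <- tri
  sigma <- 0.2
  resid_sd <- vapply(c(4, 16, 64), function(n) {
    mean(replicate(6, {
      pk <- seq(200, by = 110, length.out = n)
      vv <- numeric(max(pk) + 200)
      for (p in pk) vv[(p - 5):(p + 5)] <- vv[(p - 5):(p + 5)] + template
      vv <- vv + rnorm(length(vv), 0, sigma)
      trn <- processed(vv, rate = rate)
      ss <- new("SpikeSet", peakTimes = (pk - 1) / rate,
                peakIndices = as.integer(pk), amplitudes = rep(1, n),
                tauDecay = rep(NA_real_, n), threshold = rep(0, length(vv)),
                rate = rate, duration = length(vv) / rate)
      sh <- eventShape(trn, ss, pre = 0.5, post = 0.5)
      full <- numeric(101); full[46:56] <- template
      sd(sh@waveform - full)
    }))
  }, numeric(1))
  ## expected SD is sigma/sqrt(n): successive ratios of 2, within 20%
  expect_lt(abs(resid_sd[1] / resid_sd[2] - 2) / 2, 0.20)
  expect_lt(abs(resid_sd[2] / resid_sd[3] - 2) / 2, 0.20)
  expect_lt(abs(resid_sd[3] - sigma / 8) / (sigma / 8), 0.20)

  expect_error(eventShape(tr, sset, pre = 50, post = 50), "inside the trace")
})

test_that("averaged noisy events reproduce the template", {
  set.seed(56)
  rate <- 100
  tri <- c(seq(0, 1, length.out = 6), seq(0.8, 0, length.out = 5))
  pk <- seq(100, by = 40, length.out = 50)
  v <- numeric(max(pk) + 100)
  for (p in pk) v[(p - 5):(p + 5)] <- v[(p - 5):(p + 5)] + tri
  v <- v + rnorm(length(v), 0, 0.15)
  tr <- processed(v, rate = rate)
  ss <- new("SpikeSet", peakTimes = (pk - 1) / rate,
            peakIndices = as.integer(pk), amplitudes = rep(1, 50),
            tauDecay = rep(NA_real_, 50), threshold = rep(0, length(v)),
            rate = rate, duration = length(v) / rate)
  es <- eventShape(tr, ss, pre = 0.05, post = 0.05)
  expect_gt(cor(es@waveform, tri), 0.99)
  expect_equal(mean(es@sd), 0.15, tolerance = 0.05)
})
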