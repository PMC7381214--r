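test_that("temporal crop keeps the half-open window and resets the clock", {
  tr <- RawTrace(seq_len(1000), rate = 100)  # 10 s
  cr <- cropTime(tr, 2, 5)
  expect_equal(nSamples(cr), 300)
  expect_equal(traceValues(cr)[1], 201)  # sample at t = 2.00 s
  expect_equal(timeAxis(cr)[1], 0)

  ## identity crop
  expect_equal(traceValues(cropTime(tr, 0, 10)), traceValues(tr))

  ## crop composition: crop [1,8) then [2,5) == crop [3,6)
  twice <- cropTime(cropTime(tr, 1, 8), 2, 5)
  once <- cropTime(tr, 3, 6)
  expect_equal(traceValues(twice), traceValues(once))

  expect_error(cropTime(tr, 5, 2), "start < end")
  expect_error(cropTime(tr, 0, 11), "duration")

  ## stacks crop the same way
  st <- FrameStack(array(rep(1:20, each = 4), c(20, 2, 2)), rate = 2)
  expect_equal(nFrames(cropTime(st, 1, 5)), 8)
})

test_that("background subtraction removes contamination, preserves level", {
  set.seed(31)
  ## constant background: identity at any scale
  sig <- RawTrace(rnorm(200, 100), rate = 50)
  bg <- RawTrace(rep(42, 200), rate = 50)
  expect_equal(traceValues(subtractBackground(sig, bg, 0.7)),
               traceValues(sig))
  ## scale 0: identity
  bg2 <- RawTrace(rnorm(200, 42), rate = 50)
  expect_equal(traceValues(subtractBackground(sig, bg2, 0)),
               traceValues(sig))

  ## synthetic contamination: signal = cell + 0.5 contaminant
  t <- seq(0, 20, by = 0.02)[-1]
  cell <- 0.1 * sin(2 * pi * 0.5 * t) + 0.02 * rnorm(length(t))
  contaminant <- 0.2 * sin(2 * pi * 1.3 * t)
  s <- RawTrace(100 + cell + 0.5 * contaminant, rate = 50)
  b <- RawTrace(30 + contaminant, rate = 50)
  out <- subtractBackground(s, b, 0.5)
  expect_gt(cor(traceValues(out), cell), 0.99)
  expect_equal(mean(traceValues(out)), mean(traceValues(s)), tolerance = 1e-9)

  expect_error(subtractBackground(s, RawTrace(1:10, 50)), "length")
})

test_that("baseline families fit their exact members and recover bleaching", {
  ## constant trace, degree-0 polynomial
  ct <- RawTrace(rep(3.5, 100), rate = 10)
  b0 <- fitBaseline(ct, "polynomial", degree = 0)
  expect_equal(b0@fitted, rep(3.5, 100), tolerance = 1e-12)

  ## linear ramp is exact for degree 1
  ramp <- RawTrace(5 + 0.3 * (0:99), rate = 10)
  b1 <- fitBaseline(ramp, "polynomial", degree = 1)
  expect_lt(max(abs(b1@fitted - traceValues(ramp))), 1e-9)

  ## mono-exponential recovery at SNR 10: F = 100 exp(-0.2 t) + events
  set.seed(32)
  t <- seq(0, 20, by = 0.01)[-1]
  events <- numeric(length(t))
  onsets <- seq(1, 19, by = 1.5)
  for (on in onsets) {
    idx <- t >= on & t < on + 0.4
    events[idx] <- events[idx] + sin(pi * (t[idx] - on) / 0.4)
  }
  events <- events - mean(events)
  F <- 100 * exp(-0.2 * t) + events  # event SD ~ amplitude/10 of baseline span
  bm <- fitBaseline(RawTrace(F, rate = 100), "mono_exponential")
  expect_lt(abs(bm@params$b - 0.2) / 0.2, 0.05)
  expect_gte(bm@params$b, 0)

  ## marker spline interpolates the local median at the markers
  y <- 10 + 0.001 * (0:199) + rnorm(200, 0, 1e-4)
  mtr <- RawTrace(y, rate = 100)
  marks <- c(10L, 80L, 150L, 190L)
  ms <- fitBaseline(mtr, "marker_spline", markers = marks)
  for (m in marks)
    expect_equal(ms@fitted[m], median(y[(m - 2):(m + 2)]), tolerance = 1e-9)

  ## least-squares families beat the constant-mean baseline
  rss <- sum((traceValues(ramp) - b1@fitted)^2)
  rss0 <- sum((traceValues(ramp) - mean(traceValues(ramp)))^2)
  expect_lte(rss, rss0)

  expect_error(fitBaseline(RawTrace(1:3, 10), "mono_exponential"), "few samples")
})

test_that("dF/F is (F - F0)/F0 with optional inversion", {
  tr <- RawTrace(rep(110, 50), rate = 10)
  bl <- new("BaselineModel", kind = "polynomial", params = list(),
            fitted = rep(100, 50), markers = integer())
  p <- computeDFF(tr, bl)
  expect_equal(traceValues(p), rep(0.10, 50))
  expect_false(p@inverted)

  ## F == baseline gives zeros
  tr0 <- RawTrace(rep(100, 50), rate = 10)
  expect_true(all(traceValues(computeDFF(tr0, bl)) == 0))

  ## inversion is an involution
  pi1 <- computeDFF(tr, bl, invert = TRUE)
  expect_equal(traceValues(pi1), rep(-0.10, 50))
  expect_equal(traceValues(invertTrace(pi1)), traceValues(p))

  badbl <- new("BaselineModel", kind = "polynomial", params = list(),
               fitted = c(rep(100, 49), 0), markers = integer())
  expect_error(computeDFF(tr, badbl), "nonpositive")
})

test_that("dF/F of a bleach-only trace has no residual trend", {
  t <- seq(0, 30, by = 0.02)[-1]
  F <- RawTrace(200 * exp(-0.15 * t), rate = 50)
  bm <- fitBaseline(F, "mono_exponential")
  p <- computeDFF(F, bm)
  slope <- coef(lm(traceValues(p) ~ timeAxis(p)))[2]
  expect_lt(abs(slope), 1e-3)
})

test_that("filters are zero-phase and reproduce their invariants", {
  ## Savitzky-Golay reproduces a quadratic on interior samples
  q <- processed((seq(0, 1, length.out = 101))^2, rate = 100)
  sg <- applyFilter(q, "savitzky_golay", window = 7, polyorder = 2)
  expect_lt(max(abs(traceValues(sg) - traceValues(q))[4:98]), 1e-9)

  ## moving average preserves constants (both tapers)
  cst <- processed(rep(2, 60), rate = 10)
  for (tp in c("flat", "hann"))
    expect_equal(traceValues(applyFilter(cst, "moving_average", window = 5,
                                         taper = tp)), rep(2, 60))

  ## band-pass isolates the in-band component
  r <- 100
  t <- seq(0, 30, by = 1 / r)[-1]
  mix <- processed(sin(2 * pi * 1 * t) + sin(2 * pi * 10 * t), rate = r)
  bp <- applyFilter(mix, "band_pass", low = 0.5, high = 2)
  keep <- t > 1 & t < 29  # trim 1 s edges
  expect_gt(cor(traceValues(bp)[keep], sin(2 * pi * 1 * t)[keep]), 0.99)

  ## zero-phase contract: in-band sinusoid keeps its peak position
  tone <- processed(sin(2 * pi * 1 * t), rate = r)
  filt <- applyFilter(tone, "band_pass", low = 0.5, high = 2)
  xc <- ccf(traceValues(filt)[keep], traceValues(tone)[keep], lag.max = 20,
            plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)

  expect_error(applyFilter(q, "savitzky_golay", window = 6), "odd")
  expect_error(applyFilter(q, "band_pass", low = 2, high = 1), "low < high")
  expect_error(applyFilter(q, "low_pass", cutoff = 100), "rate/2")
})

test_that("resampling interpolates on the new grid", {
  ## linear ramp downsampled is exact
  ramp <- processed(0:99, rate = 100)  # value = 100 * t
  down <- resampleTrace(ramp, 50, "linear")
  expect_equal(sampleRate(down), 50)
  expect_equal(traceValues(down), seq(0, 98, by = 2), tolerance = 1e-12)
  expect_lt(abs(duration(down) - duration(ramp)), 1 / 50 + 1e-12)

  ## identity at the same rate
  set.seed(33)
  x <- processed(rnorm(100), rate = 100)
  expect_equal(traceValues(resampleTrace(x, 100, "linear")), traceValues(x),
               tolerance = 1e-12)

  ## cubic vs closed form for a 1 Hz sine
  t <- seq(0, 9.99, by = 0.01)  # sample i at t = (i-1)/rate
  sine <- processed(sin(2 * pi * t), rate = 100)
  cub <- resampleTrace(sine, 25, "cubic")
  expect_lt(max(abs(traceValues(cub) - sin(2 * pi * timeAxis(cub)))), 1e-3)

  expect_error(resampleTrace(x, 0.5), "fewer than 2")
})

test_that("resampling suggestions follow the two stated rules", {
  expect_identical(suggestResampling("event_intervals", signalFreq = 1), 2)
  expect_identical(suggestResampling("event_shape", shortestEvent = 0.05), 200)
  expect_identical(
    suggestResampling("combined", signalFreq = 1, shortestEvent = 0.05), 200)
  ## combined takes the larger rule either way round
  expect_identical(
    suggestResampling("combined", signalFreq = 500, shortestEvent = 0.05), 1000)
  expect_error(suggestResampling("event_intervals"), "signalFreq")
  expect_error(suggestResampling("event_shape", shortestEvent = -1),
               "shortestEvent")
})

test_that("offset alignment shifts the electrode clock and reports overlap", {
  r <- 200
  t <- seq(0, 10, by = 1 / r)[-1]
  wave <- sin(2 * pi * 1.5 * t) * exp(-0.05 * t)
  opt <- processed(wave, rate = r)
  ## electrode trace = optical waveform delayed by 0.1 s
  ele <- ElectrodeTrace(c(rep(0, 0.1 * r), wave)[seq_along(t)], rate = r)

  ## offset 0 keeps values untouched
  al0 <- alignOffset(opt, ele, 0)
  expect_equal(traceValues(al0), traceValues(ele))
  expect_equal(al0@offset, 0)

  ## aligning by -0.1 s puts the cross-correlation peak at lag 0
  al <- alignOffset(opt, ele, -0.1)
  pair <- extractOverlap(opt, al)
  xc <- amplitudeXcorr(pair$optical, pair$electrode, maxLag = 0.5)
  expect_equal(xc@lags[which.max(xc@values)], 0, tolerance = 1 / r + 1e-12)

  expect_error(alignOffset(opt, ele, 10), "smaller than")
})

test_that("the pipeline order is enforced and provenance is recorded", {
  tr <- RawTrace(100 + rnorm(300), rate = 100, label = "cellA")
  bl <- fitBaseline(tr, "polynomial", degree = 0)
  p <- computeDFF(tr, bl)
  f <- applyFilter(p, "moving_average", window = 3)
  rs <- resampleTrace(f, 50)
  ops <- vapply(traceSteps(rs), function(s) s$op, character(1))
  expect_equal(ops, c("baseline", "dff", "filter", "resample"))

  ## cropping after filtering violates the order
  expect_error(cropTime(f, 0, 1), "ordering")
  ## background subtraction after dF/F violates the order
  expect_error(subtractBackground(
    RawTrace(rnorm(10), 10, steps = list(list(op = "filter", params = list()))),
    RawTrace(rnorm(10), 10)), "ordering")

  ## one parameter set applied to several ROIs: identical provenance
  apply_chain <- function(lab) {
    x <- RawTrace(100 + rnorm(300), rate = 100, label = lab)
    x <- cropTime(x, 0, 2)
    b <- fitBaseline(x, "polynomial", degree = 1)
    x <- computeDFF(x, b)
    applyFilter(x, "moving_average", window = 5)
  }
  s1 <- apply_chain("roi1"); s2 <- apply_chain("roi2")
  expect_identical(traceSteps(s1), traceSteps(s2))
  expect_false(identical(traceLabel(s1), traceLabel(s2)))
})
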