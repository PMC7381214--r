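test_that("a bleach-only spec produces exactly the bleach curve", {
  sp <- SynthSpec(duration = 5, rate = 100, components = list(),
                  bleach = c(a = 200, b = 0.3), noiseSd = 0, seed = 1)
  out <- synthTrace(sp)
  t <- timeAxis(out$trace)
  expect_equal(traceValues(out$trace), 200 * exp(-0.3 * t), tolerance = 1e-12)
  expect_equal(out$truth$signal, rep(0, 500))
})

test_that("equal specs are bit-reproducible; inversion flips the signal", {
  sp <- SynthSpec(duration = 4, rate = 50,
                  components = list(oscillation(1, 0.1),
                                    spikeComponent(poissonRate = 2, amp = 0.05)),
                  bleach = c(a = 100, b = 0.05), noiseSd = 2, seed = 99)
  out1 <- synthTrace(sp)
  out2 <- synthTrace(sp)
  expect_identical(traceValues(out1$trace), traceValues(out2$trace))
  expect_identical(out1$truth$spikes, out2$truth$spikes)

  ## inverted reporter: F dips where the signal rises
  spInv <- SynthSpec(duration = 4, rate = 50,
                     components = list(oscillation(1, 0.2)),
                     bleach = c(a = 100, b = 0), noiseSd = 0, invert = TRUE,
                     seed = 99)
  outI <- synthTrace(spInv)
  expect_equal(traceValues(outI$trace), 100 * (1 - outI$truth$signal),
               tolerance = 1e-12)
})

test_that("burst ground truth matches the analysis schema and is recoverable", {
  ## end-to-end: bleaching + bursts -> marker baseline -> dF/F ->
  ## detection. Markers sit between bursts, the use case they exist for.
  sp <- SynthSpec(duration = 20, rate = 100,
                  components = list(burstComponent(
                    starts = c(3, 8, 13), width = 2.5, aMax = 0.2,
                    tPeak = 0.2, b = 2)),
                  bleach = c(a = 300, b = 0.05), noiseSd = 0.6, seed = 5)
  out <- synthTrace(sp)
  expect_named(out$truth$bursts,
               c("start_s", "end_s", "a_max", "t_peak_s", "tau_decay_s"))
  expect_equal(out$truth$bursts$tau_decay_s, rep(0.5, 3))

  markers <- round(c(0.5, 6.8, 11.8, 16.8, 19.5) * 100)
  bl <- fitBaseline(out$trace, "marker_spline", markers = markers)
  p <- computeDFF(out$trace, bl)
  th <- makeThreshold(p, "static", level = 0.02)
  bursts <- detectBursts(p, th, minDuration = 0.5, endFraction = 0.1)
  tb <- burstTable(bursts)
  expect_equal(nrow(tb), 3)
  expect_lt(abs(median(tb$tauDecay) - 0.5) / 0.5, 0.05)
  expect_lt(max(abs(tb$tauDecay - 0.5) / 0.5), 0.10)
  ## peak time on the absolute clock (burst start is a threshold
  ## crossing, so it lags the component onset slightly)
  expect_lt(max(abs((tb$start + tb$tPeak) -
                    (out$truth$bursts$start_s + 0.2))), 0.03)
  expect_lt(max(abs(tb$aMax - 0.2) / 0.2), 0.10)
})

test_that("movies place cells, mix scatter and roll movement as specified", {
  mkspec <- function(seed, comps) {
    SynthSpec(duration = 2, rate = 50, components = comps,
              bleach = c(a = 400, b = 0.02), noiseSd = 0, seed = seed)
  }
  ## one static cell, no noise: ROI mean is an affine map of its trace
  sp <- mkspec(3, list(oscillation(2, 0.2)))
  mv <- synthMovie(list(synthCell(c(10, 10), 2, sp)), c(20, 20),
                   offset = 30, noiseSd = 0, seed = 3, quantize = FALSE)
  roi <- Roi("ellipse", label = "c", center = c(10, 10), semiAxes = c(3, 3))
  tr <- traceValues(extractTrace(mv$stack, roi))
  expect_equal(cor(tr, mv$truth$fluo[, 1]), 1, tolerance = 1e-9)

  ## known integer shifts are recovered exactly across modules
  set.seed(33)
  movement <- cbind(sample(-2:2, 100, TRUE), sample(-2:2, 100, TRUE))
  movement[1, ] <- 0
  spm <- mkspec(4, list(oscillation(1, 0.3)))
  mvm <- synthMovie(list(synthCell(c(16, 16), 3, spm)), c(32, 32),
                    movement = movement, offset = 40, noiseSd = 0.5, seed = 4)
  est <- estimateShifts(mvm$stack, maxShift = 3, subpixel = FALSE)
  expect_equal(shiftMatrix(est), movement)
  expect_identical(mvm$truth$shifts, movement)

  ## scatter mixing: cell B's ROI trace contains 0.5 of cell A
  spA <- mkspec(5, list(oscillation(1.5, 0.3)))
  spB <- mkspec(6, list(oscillation(0.5, 0.3)))
  scatter <- rbind(c(1, 0), c(0.5, 1))  # row i: weights of traces under cell i
  mv2 <- synthMovie(list(synthCell(c(10, 10), 2, spA),
                         synthCell(c(10, 26), 2, spB)),
                    c(20, 36), scatter = scatter, offset = 30, noiseSd = 0,
                    seed = 7, quantize = FALSE)
  expect_equal(mv2$truth$mixed[, 2],
               mv2$truth$fluo[, 2] + 0.5 * mv2$truth$fluo[, 1],
               tolerance = 1e-12)
  roiB <- Roi("ellipse", label = "B", center = c(10, 26), semiAxes = c(3, 3))
  trB <- traceValues(extractTrace(mv2$stack, roiB))
  expect_equal(cor(trB, mv2$truth$mixed[, 2]), 1, tolerance = 1e-6)

  expect_error(synthMovie(list(synthCell(c(50, 10), 2, spA)), c(20, 36)),
               "outside")
})

test_that("perisomatic subtraction undoes scatter; smoothing alone cannot", {
  ## cell A oscillates slowly, cell B bursts; 0.5 of A contaminates B.
  ## The annulus around A samples A's signal, and with the kernel-derived
  ## scale the subtraction restores B's clean trace.
  rate <- 50
  mk <- function(seed, comps) SynthSpec(duration = 10, rate = rate,
                                        components = comps,
                                        bleach = c(a = 400, b = 0),
                                        noiseSd = 0, seed = seed)
  spA <- mk(8, list(oscillation(1.1, 0.25)))
  spB <- mk(9, list(burstComponent(starts = c(1, 4, 7), width = 2,
                                   aMax = 0.25, tPeak = 0.3, b = 2)))
  scatter <- rbind(c(1, 0), c(0.5, 1))
  shape <- c(24, 44)
  cells <- list(synthCell(c(12, 12), 2.5, spA), synthCell(c(12, 32), 2.5, spB))
  mv <- synthMovie(cells, shape, scatter = scatter, offset = 30,
                   noiseSd = 1.5, seed = 10)

  ## a tight ROI around A keeps its annulus on the bright part of A's
  ## kernel, so the subtraction scale stays a fraction in [0, 1]
  roiA <- Roi("ellipse", label = "A", center = c(12, 12), semiAxes = c(2, 2))
  roiB <- Roi("ellipse", label = "B", center = c(12, 32), semiAxes = c(4, 4))
  maskA <- makeMask(roiA, shape); maskB <- makeMask(roiB, shape)
  annA <- perisomaticAnnulus(roiA, 2, shape, exclude = list(roiB))

  sigB <- extractTrace(mv$stack, roiB)
  bgA <- extractTrace(mv$stack, annA)

  ## scale from the known kernels: contamination of B's ROI mean is
  ## 0.5 * kB * fluoA, the annulus carries kAnn * fluoA
  kB <- mean(mv$truth$kernels[[2]][maskB])
  kAnn <- mean(mv$truth$kernels[[1]][annA])
  scale <- 0.5 * kB / kAnn
  expect_lte(scale, 1)
  corrected <- subtractBackground(sigB, bgA, scale = scale)

  cleanB <- mv$truth$fluo[, 2]
  expect_gt(cor(traceValues(corrected), cleanB), 0.99)

  ## smoothing alone keeps the contamination
  smoothed <- applyFilter(sigB, "moving_average", window = 5)
  expect_lt(cor(traceValues(smoothed), cleanB), 0.95)
})
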