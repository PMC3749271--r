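makeSine <- function(freq, fs = 256, secs = 8) {
  tt <- (0:(secs * fs - 1)) / fs
  new("Recording", X = matrix(sin(2 * pi * freq * tt), 1), fs = fs,
      channelLabels = "x")
}

test_that("band-pass gain matches the designed frequency response", {
  spec <- filterSpec()
  # pass band: 6 Hz preserved within 2 percent, and equal to the oracle
  r6 <- bandpassFilter(makeSine(6), spec)
  amp6 <- diff(range(recData(r6)[1, 1025:1536])) / 2  # interior samples
  expect_lt(abs(amp6 - 1), 0.02)
  expect_equal(amp6, filterResponse(spec, 6), tolerance = 0.01)

  # stop band: 50 Hz attenuated by >= 40 dB, matching the oracle
  r50 <- bandpassFilter(makeSine(50), spec)
  amp50 <- diff(range(recData(r50)[1, 1025:1536])) / 2
  expect_lt(20 * log10(amp50), -40)
  expect_equal(amp50, filterResponse(spec, 50), tolerance = 0.1)

  # geometric mid-band gain within 1 percent of unity
  expect_lt(abs(filterResponse(spec, sqrt(1 * 12)) - 1), 0.01)

  # zero in, zero out
  z <- new("Recording", X = matrix(0, 2, 512), fs = 256,
           channelLabels = c("a", "b"))
  expect_true(all(recData(bandpassFilter(z)) == 0))

  expect_error(bandpassFilter(makeSine(6), filterSpec(highHz = 200)),
               "Nyquist")
})

test_that("filtering is time-invariant on interior samples", {
  set.seed(1)
  x <- rnorm(4096)
  shift <- 32L
  rec1 <- new("Recording", X = matrix(x, 1), fs = 256, channelLabels = "x")
  rec2 <- new("Recording", X = matrix(c(rep(0, shift), x), 1), fs = 256,
              channelLabels = "x")
  y1 <- recData(bandpassFilter(rec1))[1, ]
  y2 <- recData(bandpassFilter(rec2))[1, ]
  idx <- 1001:3000
  expect_equal(y1[idx], y2[idx + shift], tolerance = 1e-6)
})

test_that("filtered broadband power drops by the response-predicted factor", {
  set.seed(2)
  n <- 2^16
  x <- rnorm(n)
  rec <- new("Recording", X = matrix(x, 1), fs = 256, channelLabels = "x")
  y <- recData(bandpassFilter(rec))[1, ]
  # white input: RMS ratio is the RMS of the zero-phase gain over frequency
  f <- seq(0.01, 128, length.out = 2048)
  g <- filterResponse(filterSpec(), f)
  expect_equal(sd(y) / sd(x), sqrt(mean(g^2)), tolerance = 0.1)
})

test_that("epoch extraction follows the closed-window sample convention", {
  fs <- 256
  ev <- generateStimulusSequence(1, seed = 1, firstOnset = 1.0)
  x <- matrix(seq_len(8 * fs), 1) * 1.0
  rec <- new("Recording", X = x, fs = fs, channelLabels = "x")
  ep <- extractEpochs(rec, ev, window = c(0, 0.7), baseline = c(0, 0.1))
  expect_equal(dim(epochData(ep)), c(7L, 1L, 180L))  # round(0.7*256)+1

  # constant channel: baseline correction zeroes every epoch
  recC <- new("Recording", X = matrix(5, 1, 8 * fs), fs = fs,
              channelLabels = "x")
  epC <- extractEpochs(recC, ev, window = c(-0.1, 0.7))
  expect_true(all(epochData(epC) == 0))

  # windows outside the recording are reported with the offending events
  expect_error(extractEpochs(rec, ev, window = c(-2, 0.7)), "events 1")
})

test_that("target epochs of the simulated ERP peak inside 250-450 ms", {
  sess <- makeSession(4, nBlocks = 5)
  erp <- new("Recording", X = sources(sess$sources)[1, , drop = FALSE],
             fs = 256, channelLabels = "erp")
  ep <- extractEpochs(erp, sess$events, window = c(-0.1, 0.7))
  tt <- epochTimes(ep)
  for (e in which(isTarget(sess$events))) {
    pk <- tt[which.max(epochData(ep)[e, 1, ])]
    expect_gt(pk, 0.250)
    expect_lt(pk, 0.450)
  }
})
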