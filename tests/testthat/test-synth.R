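test_that("stimulus schedules have oddball structure and fixed spacing", {
  ev <- generateStimulusSequence(1, isi = 0.350, seed = 3)
  expect_s4_class(ev, "EventSequence")
  expect_length(ev, 7)
  expect_equal(diff(onsets(ev)), rep(0.350, 6))
  expect_setequal(stimulusIds(ev), 1:7)

  ev3 <- generateStimulusSequence(3, isi = 0.375, seed = 11)
  expect_length(ev3, 21)
  # each block a permutation; one constant target across blocks
  for (b in 0:2)
    expect_setequal(stimulusIds(ev3)[blockIds(ev3) == b], 1:7)
  expect_equal(sum(isTarget(ev3)), 3)
  expect_true(targetId(ev3) %in% 1:7)

  # empty and deterministic cases
  expect_length(generateStimulusSequence(0, seed = 1), 0)
  expect_identical(generateStimulusSequence(3, seed = 5),
                   generateStimulusSequence(3, seed = 5))
  expect_false(identical(stimulusIds(generateStimulusSequence(3, seed = 5)),
                         stimulusIds(generateStimulusSequence(3, seed = 6))))

  expect_error(generateStimulusSequence(1, isi = 0.350,
                                        flashDuration = 0.010),
               "inconsistent")
  expect_error(generateStimulusSequence(1, isi = 0.6), "isi")
})

test_that("the ERP source is a template locked to target onsets", {
  # one block whose target happens at a known onset
  ev <- generateStimulusSequence(1, isi = 0.350, seed = 2, firstOnset = 0.3)
  src <- generateSources(ev, duration = 4, seed = 7)
  S <- sources(src)
  expect_identical(sourceKinds(src)[1], "erp")
  tOn <- onsets(ev)[isTarget(ev)]
  tt <- (seq_len(ncol(S)) - 1) / samplingRate(src)
  peakT <- tt[which.max(S[1, ])]
  expect_lt(abs(peakT - (tOn + 0.300)), 1 / samplingRate(src) + 1e-9)

  # zero-amplitude ERP gives an identically-zero row
  src0 <- generateSources(ev, duration = 4, seed = 7,
                          params = sourceParams(p300Uv = 0,
                                                orthogonalize = FALSE))
  expect_true(all(sources(src0)[1, ] == 0))

  expect_error(generateSources(ev, duration = 1, seed = 1), "too short")
})

test_that("generated sources are zero-mean, decorrelated, realistic in scale", {
  ev <- generateStimulusSequence(20, seed = 2, firstOnset = 0.5)
  src <- generateSources(ev, duration = 60, seed = 3)
  S <- sources(src)
  expect_equal(nrow(S), 4)
  expect_true(all(abs(rowMeans(S)) < 1e-6 * sqrt(rowMeans(S^2))))
  # mutual decorrelation over >= 60 s
  offDiag <- abs(cor(t(S)))[upper.tri(diag(4))]
  expect_true(all(offDiag < 0.1))
  # raw background peak-to-peak near 300 uV
  for (i in which(sourceKinds(src) == "background"))
    expect_true(diff(range(S[i, ])) > 200 && diff(range(S[i, ])) < 400)
  # bit-identical regeneration under the same seed
  expect_identical(S, sources(generateSources(ev, duration = 60, seed = 3)))
})

test_that("mixing matrices are well-conditioned with unit-norm columns", {
  m <- makeMixing(M = 2, N = 2, seed = 1, condBound = 10)
  A <- mixingMatrix(m)
  expect_equal(dim(A), c(2L, 2L))
  expect_lte(kappa(A, exact = TRUE), 10)

  m2 <- makeMixing(M = 8, N = 4, seed = 9)
  A2 <- mixingMatrix(m2)
  expect_equal(qr(A2)$rank, 4L)
  expect_equal(colSums(A2^2), rep(1, 4))
  expect_lte(kappa(A2, exact = TRUE), 10)

  expect_identical(mixingMatrix(makeMixing(8, 4, seed = 3)),
                   mixingMatrix(makeMixing(8, 4, seed = 3)))
  expect_error(makeMixing(M = 2, N = 4), "dimension")
})

test_that("mixing reproduces X = A S + n with the stated noise model", {
  fs <- 256
  tt <- (0:4095) / fs
  # two orthogonal unit sines -> hand-computable channel covariance
  S <- rbind(sin(2 * pi * 8 * tt), cos(2 * pi * 8 * tt))
  src <- new("SourceSet", S = S - rowMeans(S), kinds = c("background",
                                                         "background"),
             fs = fs)
  A <- matrix(c(1, 1, 1, -1), 2) / sqrt(2)
  mod <- new("MixtureModel", A = A, noiseSigma = 0, seed = 1L)
  rec <- mixSources(src, mod)
  # expected covariance A diag(1/2, 1/2) A^T = I/2
  expect_equal(tcrossprod(recData(rec)) / ncol(S),
               diag(2) / 2, tolerance = 1e-3)

  # identity mixing, no noise: X equals S exactly
  modI <- new("MixtureModel", A = diag(2), noiseSigma = 0, seed = 1L)
  expect_identical(recData(mixSources(src, modI)), unname(sources(src)))

  # residual sd matches noiseSigma over 10^4+ samples
  modN <- new("MixtureModel", A = diag(2), noiseSigma = 3, seed = 1L)
  recN <- mixSources(src, modN, seed = 42)
  resid <- recData(recN) - sources(src)
  expect_lt(abs(sd(resid) - 3) / 3, 0.05)

  expect_error(mixSources(src, new("MixtureModel", A = diag(3),
                                   noiseSigma = 0, seed = 1L)),
               "mismatch")
})

test_that("mixing is linear and seeded sessions are reproducible", {
  ev <- generateStimulusSequence(2, seed = 1, firstOnset = 0.4)
  s1 <- generateSources(ev, duration = 6, seed = 1)
  s2 <- generateSources(ev, duration = 6, seed = 2)
  mod <- makeMixing(6, 4, seed = 3)
  lhsS <- new("SourceSet", S = 2 * sources(s1) + 0.5 * sources(s2),
              kinds = sourceKinds(s1), fs = 256)
  lhs <- recData(mixSources(lhsS, mod))
  rhs <- 2 * recData(mixSources(s1, mod)) +
    0.5 * recData(mixSources(s2, mod))
  expect_equal(lhs, rhs, tolerance = 1e-12)

  a <- makeSession(5); b <- makeSession(5)
  expect_identical(recData(a$recording), recData(b$recording))
})
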