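test_that("SOBI separates temporally distinct sources", {
  set.seed(1)
  n <- 8000
  s1 <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  s2 <- as.numeric(stats::filter(rnorm(n), -0.6, method = "recursive"))
  S <- rbind(s1, s2); S <- S - rowMeans(S)
  S[2, ] <- S[2, ] - sum(S[2, ] * S[1, ]) / sum(S[1, ]^2) * S[1, ]
  S <- S / apply(S, 1, sd)
  src <- new("SourceSet", S = S, kinds = rep("background", 2), fs = 256)
  Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  mod <- new("MixtureModel", A = Q, noiseSigma = 0, seed = 1L)
  rec <- mixSources(src, mod)
  b <- sobi(rec, truth = list(sources = src, model = mod))
  expect_lt(utils::tail(b@piCurve$pi, 1), 0.05)

  # identity mixture: essentially separated after the first sweep
  modI <- new("MixtureModel", A = diag(2), noiseSigma = 0, seed = 1L)
  recI <- mixSources(src, modI)
  bI <- sobi(recI, truth = list(sources = src, model = modI))
  expect_lt(bI@piCurve$pi[1], 0.05)
})

test_that("SOBI flags non-identifiable lag structure", {
  x <- exactWhite(3, 6000, seed = 3)
  src <- new("SourceSet", S = x, kinds = rep("background", 3), fs = 256)
  mod <- new("MixtureModel", A = qr.Q(qr(matrix(rnorm(9), 3))),
             noiseSigma = 0, seed = 1L)
  rec <- mixSources(src, mod)
  b <- suppressWarnings(sobi(rec, truth = list(sources = src, model = mod)))
  # white sources: rotations carry no information, PI stays high
  expect_gt(utils::tail(b@piCurve$pi, 1), 0.1)
  expect_error(sobi(rec, lags = 1), "lags")
})

test_that("plain NPCA is reproducible and fails on Gaussian-only sources", {
  sess <- makeSession(4)
  truth <- truthOf(sess)
  a <- plainNpca(sess$recording, passes = 1, truth = truth)
  b <- plainNpca(sess$recording, passes = 1, truth = truth)
  expect_identical(a@piCurve, b@piCurve)

  set.seed(5)
  S <- matrix(rnorm(3 * 6000), 3)
  S <- S - rowMeans(S)
  src <- new("SourceSet", S = S, kinds = rep("background", 3), fs = 256)
  mod <- new("MixtureModel", A = qr.Q(qr(matrix(rnorm(9), 3))),
             noiseSigma = 0, seed = 1L)
  g <- plainNpca(mixSources(src, mod), passes = 1,
                 truth = list(sources = src, model = mod))
  expect_gt(utils::tail(g@piCurve$pi, 1), 0.1)
})

test_that("the comparison table is deterministic and well-formed", {
  tab1 <- compareAlgorithms(algorithms = "sobi", seeds = 1)
  expect_equal(nrow(tab1), 1L)
  expect_named(tab1, c("algorithm", "seed", "finalPi", "itersTo0.1",
                       "itersTo0.05"))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  tab2 <- compareAlgorithms(algorithms = c("sobi", "plain_npca"),
                            seeds = c(1, 2), file = f)
  tab3 <- compareAlgorithms(algorithms = c("sobi", "plain_npca"),
                            seeds = c(1, 2))
  expect_identical(tab2[, -1], tab3[, -1])
  expect_identical(tab2$algorithm, tab3$algorithm)
  expect_true(file.exists(f))
})

test_that("external algorithms can be registered and dispatched", {
  registerBaseline("mock", function(rec, truth = NULL, seed = 1, ...) {
    new("BaselineResult", algorithm = "mock", W = diag(nChannels(rec)),
        piCurve = data.frame(iteration = 1, pi = 0.5),
        iterationsToThreshold = c("0.1" = NA_real_, "0.05" = NA_real_))
  })
  expect_true("mock" %in% listBaselines())
  tab <- compareAlgorithms(algorithms = "mock", seeds = 1)
  expect_equal(tab$finalPi, 0.5)
})

test_that("joint diagonalization matches eigen on a single matrix", {
  set.seed(6)
  M <- crossprod(matrix(rnorm(9), 3))
  jd <- anpca:::jointDiagonalize(list(M))
  D <- t(jd$V) %*% M %*% jd$V
  expect_lt(max(abs(D[upper.tri(D)])), 1e-8)
  expect_equal(sort(diag(D)), sort(eigen(M)$values), tolerance = 1e-8)
})
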