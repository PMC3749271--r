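test_that("mixing estimation recovers identity and known mixings", {
  set.seed(1)
  y <- matrix(runif(3 * 4000, -sqrt(3), sqrt(3)), 3)
  est <- estimateMixing(y, y, alpha = 0.3)
  expect_lt(max(abs(est@Q - diag(3))), 0.05)

  A <- matrix(rnorm(12), 4, 3)
  est2 <- estimateMixing(y, A %*% y, alpha = 0.3, epochs = 2)
  # least-squares solution is A itself; columnwise agreement within 5 percent
  for (j in 1:3)
    expect_lt(sqrt(sum((est2@Q[, j] - A[, j])^2)) / sqrt(sum(A[, j]^2)),
              0.05)

  est0 <- estimateMixing(y, A %*% y, alpha = 0)
  expect_true(all(est0@Q == 0))   # zero rate leaves Q at its initial value
})

test_that("the combined system is the stated matrix product", {
  expect_equal(combinedSystem(diag(3), diag(3), diag(3)), diag(3))
  set.seed(2)
  W <- matrix(rnorm(6), 2, 3); P <- matrix(rnorm(9), 3, 3)
  V <- matrix(rnorm(12), 3, 4)
  expect_equal(combinedSystem(W, P, V), W %*% P %*% V)
  expect_error(combinedSystem(W, V, P), "conformable")
})

test_that("the full pipeline satisfies the zero-forcing limit", {
  sess <- makeSession(1)
  cfg <- anpcaConfig(seed = 1, passes = 2, filter = list(enabled = FALSE),
                     classify = list(enabled = FALSE),
                     input = sess$recording, events = sess$events,
                     truth = truthOf(sess))
  res <- runPipeline(cfg)
  sds <- apply(sources(sess$sources), 1, sd)
  G <- res$report@C %*% mixingMatrix(sess$model) %*% diag(sds)
  # each row and column dominated by a single entry
  expect_lt(performanceIndex(G), 0.05)
  dom <- apply(abs(G), 1, which.max)
  expect_setequal(dom, 1:4)
})

test_that("PI hits its analytic boundary values exactly", {
  for (s in 1:5) {
    n <- sample(2:6, 1)
    expect_identical(performanceIndex(randomScaledPermutation(n, s)), 0)
  }
  for (n in c(2, 4, 7))
    expect_equal(performanceIndex(matrix(1, n, n)), 1, tolerance = 1e-12)
  expect_error(performanceIndex(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("PI agrees with an independently coded brute-force evaluation", {
  set.seed(3)
  for (rep in 1:25) {
    C <- matrix(rnorm(9), 3)
    expect_equal(performanceIndex(C), bruteForcePi(C), tolerance = 1e-12)
  }
  # rectangular case, rows <= columns
  C <- matrix(rnorm(12), 3, 4)
  expect_equal(performanceIndex(C), bruteForcePi(C), tolerance = 1e-12)
})

test_that("PI is invariant to permutation, sign and global scale", {
  set.seed(4)
  C <- matrix(rnorm(16), 4)
  p <- sample(4); q <- sample(4)
  sgn <- diag(sample(c(-1, 1), 4, replace = TRUE))
  expect_equal(performanceIndex(C[p, q]), performanceIndex(C))
  expect_equal(performanceIndex(sgn %*% C %*% sgn), performanceIndex(C))
  expect_equal(performanceIndex(3.7 * C), performanceIndex(C))
  expect_gt(performanceIndex(C + 0), 0)  # generic matrices are not at 0
})

test_that("the decibel conversion is 20 log10 and inverts cleanly", {
  expect_equal(piDb(1), 0)
  expect_equal(piDb(0.1), -20)
  expect_identical(piDb(0), -Inf)
  expect_equal(piDb(0.03), -30.4576, tolerance = 1e-4)
  expect_gt(piDb(0.03), -33); expect_lt(piDb(0.03), -22)
  x <- c(-31, -22.5, -3)
  expect_equal(piDb(10^(x / 20)), x)
})

test_that("convergence detection handles flat, decaying and rising curves", {
  flat <- rep(0.04, 6)
  expect_equal(convergenceEpochs(flat)$epoch, 1L)
  # geometric halving never satisfies a 1 percent criterion
  geo <- 0.5^(1:10)
  expect_false(convergenceEpochs(geo)$converged)
  # changes 30%, 20%, 0.5%, 0.3%, 0.2%: first sustained epoch is 3
  crafted <- c(1, 0.7, 0.56, 0.5572, 0.55553, 0.554419)
  expect_equal(convergenceEpochs(crafted)$epoch, 3L)
  rising <- c(0.1, 0.2, 0.4, 0.8)
  expect_false(convergenceEpochs(rising)$converged)
  expect_error(convergenceEpochs(0.5), "2 epochs")
})

test_that("noiseless ERP epochs classify perfectly, none at chance", {
  sess <- makeSession(7, nBlocks = 8)
  erp <- new("Recording", X = sources(sess$sources)[1, , drop = FALSE],
             fs = 256, channelLabels = "erp")
  ep <- extractEpochs(erp, sess$events, window = c(-0.1, 0.7))
  cl <- classifyBlocks(ep)
  expect_equal(accuracy(cl), 1.0)
  expect_true(all(predictions(cl) == targetId(sess$events)))

  # zero-amplitude target: accuracy falls to chance (1/7)
  ev <- generateStimulusSequence(60, seed = 8, firstOnset = 0.5)
  set.seed(8)
  n <- round(256 * (max(onsets(ev)) + 1))
  noise <- new("Recording", X = matrix(rnorm(n), 1), fs = 256,
               channelLabels = "x")
  epN <- extractEpochs(noise, ev, window = c(-0.1, 0.7))
  accN <- accuracy(classifyBlocks(epN, m = 1))
  expect_gt(accN, 0.0); expect_lt(accN, 0.35)
  expect_error(classifyBlocks(ep, generateStimulusSequence(0)), "block")
})

test_that("block averaging does not hurt accuracy on noisy epochs", {
  # weak ERP in noise: accuracy should improve (or stay) as m grows
  sess <- simulateSession(nBlocks = 12, duration = 31, seed = 10,
                          noiseSigma = 0)
  erp <- sources(sess$sources)[1, , drop = FALSE]
  set.seed(11)
  rec <- new("Recording", X = erp + matrix(rnorm(ncol(erp), sd = 0.4), 1),
             fs = 256, channelLabels = "x")
  ep <- extractEpochs(rec, sess$events, window = c(-0.1, 0.7))
  acc <- classifyBlocks(ep)@accuracyByM$accuracy
  expect_gte(acc[length(acc)], acc[1])
  expect_gte(utils::tail(acc, 1), 0.8)
})
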