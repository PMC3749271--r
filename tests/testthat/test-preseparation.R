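test_that("spatial whitening is exact and idempotent up to rotation", {
  x <- exactWhite(4, 3000, seed = 1)
  sw <- spatialWhiten(x, nKeep = 4)
  B <- sw$state@B
  # already-white input: B orthonormal, output covariance the identity
  expect_equal(B %*% t(B), diag(4), tolerance = 1e-6)
  expect_equal(tcrossprod(sw$xbar) / ncol(x), diag(4), tolerance = 1e-6)
  # whitening a whitened signal again only rotates
  sw2 <- spatialWhiten(sw$xbar, nKeep = 4)
  expect_equal(sw2$state@B %*% t(sw2$state@B), diag(4), tolerance = 1e-6)
})

test_that("eigenvalues match the closed-form 2x2 solution", {
  set.seed(2)
  # build data with an exactly prescribed sample covariance
  target <- matrix(c(4, 1.2, 1.2, 2), 2)
  x <- exactWhite(2, 5000, seed = 2)
  x <- t(chol(target)) %*% x
  sw <- spatialWhiten(x, nKeep = 2)
  a <- target[1, 1]; b <- target[1, 2]; cc <- target[2, 2]
  lamHand <- (a + cc) / 2 + c(1, -1) * sqrt(((a - cc) / 2)^2 + b^2)
  expect_equal(sw$state@eigenvalues, lamHand, tolerance = 1e-8)
})

test_that("the automatic rank rule keeps all genuine sources", {
  sess <- makeSession(3)
  sw <- spatialWhiten(sess$recording, nKeep = "auto")
  expect_equal(nrow(sw$state@B), 4L)   # 8 channels, 4 noiseless sources
  expect_error(spatialWhiten(sess$recording, nKeep = 8), "rank")
})

test_that("delayed covariance has diagonal 2(1+rho) in source coordinates", {
  set.seed(5)
  n <- 20000
  s1 <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  s2 <- as.numeric(stats::filter(rnorm(n), 0.3, method = "recursive"))
  S <- rbind(s1, s2)
  S <- S - rowMeans(S)
  S[2, ] <- S[2, ] - sum(S[2, ] * S[1, ]) / sum(S[1, ]^2) * S[1, ]
  S <- S / apply(S, 1, sd)            # exactly orthonormal rows
  dr <- delayedRotation(S, tau = 1)
  rho <- vapply(1:2, function(i) cor(S[i, -1], S[i, -n]), numeric(1))
  expect_equal(sort(dr$d), sort(2 * (1 + rho)), tolerance = 0.02)

  # the recovered rotation matches a brute-force eigendecomposition of the
  # hand-built delayed covariance
  a <- S[, 2:n]; b <- S[, 1:(n - 1)]
  Rt <- a %*% t(b) / (n - 1)
  Rxt <- 2 * tcrossprod(a) / (n - 1) + Rt + t(Rt)
  eHand <- eigen((Rxt + t(Rxt)) / 2, symmetric = TRUE)
  align <- abs(t(eHand$vectors) %*% dr$state@rotation)
  expect_equal(align, diag(2), tolerance = 1e-6)
})

test_that("white-noise input leaves the rotation degenerate", {
  x <- exactWhite(3, 4000, seed = 7)
  # tolerance widened to the sampling noise of 4000-sample covariances
  expect_warning(dr <- delayedRotation(x, tau = 1, gapTol = 0.05),
                 "degenerate")
  expect_equal(dr$d, rep(2, 3), tolerance = 0.2)
  expect_true(dr$degenerate)
})

test_that("pre-separation recovers noiseless sources up to sign/permutation", {
  for (seed in c(1, 6)) {
    sess <- makeSession(seed)
    ps <- preSeparate(sess$recording)
    m <- bestMatchCor(ps$xc, sources(sess$sources))
    expect_true(all(m > 0.95))
  }
})

test_that("tracking cost gradient matches central finite differences", {
  set.seed(8)
  for (rep in 1:20) {
    v <- rnorm(4, sd = 0.7)
    x <- rnorm(4)
    g <- pcGrad(v, x)
    gNum <- vapply(1:4, function(i) {
      h <- 1e-6
      e <- numeric(4); e[i] <- h
      (pcCost(v + e, x) - pcCost(v - e, x)) / (2 * h)
    }, numeric(1))
    expect_equal(g, gNum, tolerance = 1e-5)
  }
})

test_that("the online tracker converges to the dominant eigenvector", {
  set.seed(9)
  n <- 5000
  L <- t(chol(matrix(c(3, 0.5, 0.2, 0.5, 1, 0.1, 0.2, 0.1, 0.5), 3)))
  x <- L %*% matrix(rnorm(3 * n), 3)
  x <- x - rowMeans(x)
  tr <- trackPC(x, beta = 0.002, passes = 4)
  expect_lt(abs(utils::tail(tr$norms, 1) - 1), 0.05)
  eTop <- eigen(tcrossprod(x) / n, symmetric = TRUE)$vectors[, 1]
  cosang <- abs(sum(tr$v * eTop)) / sqrt(sum(tr$v^2))
  expect_gt(cosang, cos(5 * pi / 180))  # principal angle below 5 degrees

  # starting at the fixed point: cost stays flat, steps stay tiny
  tr2 <- trackPC(x, beta = 0.002, v0 = eTop)
  expect_lt(mean(utils::tail(tr2$cost, 100)), mean(tr2$cost[1:100]) * 1.5)
  expect_lt(max(abs(1 - tr2$norms)), 0.05)

  expect_error(trackPC(x, beta = 50), "diverged")
  expect_error(trackPC(x, beta = 0.002, v0 = c(0, 0, 0)), "nonzero")
})
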