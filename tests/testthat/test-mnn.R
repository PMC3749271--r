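test_that("network construction follows the five-layer architecture", {
  m <- buildMnn(8, 4, seed = 1)
  expect_equal(m@sizes, c(8L, 16L, 4L, 16L, 8L))
  expect_identical(buildMnn(8, 4, seed = 2)@weights,
                   buildMnn(8, 4, seed = 2)@weights)
  expect_false(identical(buildMnn(8, 4, seed = 2)@weights[[1]],
                         buildMnn(8, 4, seed = 3)@weights[[1]]))
  expect_error(buildMnn(8, 8, seed = 1), "configuration")
  expect_error(buildMnn(8, 9, seed = 1), "configuration")
})

test_that("training reconstructs data on a low-dimensional linear subspace", {
  set.seed(1)
  Z <- matrix(rnorm(300 * 2), 300, 2) %*% matrix(rnorm(2 * 6), 2, 6)
  Z <- Z / max(abs(Z))
  tr <- trainMnn(buildMnn(6, 2, seed = 1), Z, epochs = 6000)
  expect_lt(utils::tail(tr$loss, 1), 1e-3 * mean(apply(Z, 2, var)))
  # the bottleneck recovers the 2-d latent coordinates up to an affine map
  pcs <- extractNonlinearPcs(tr$model, Z)
  for (j in 1:6) {
    fit <- stats::lm.fit(cbind(1, pcs), Z[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((Z[, j] - mean(Z[, j]))^2)
    expect_gt(r2, 0.99)
  }
})

test_that("zero epochs leave the model untouched and loss never ends higher", {
  set.seed(2)
  X <- matrix(rnorm(200 * 4), 200, 4) / 4
  m <- buildMnn(4, 2, seed = 5)
  tr0 <- trainMnn(m, X, epochs = 0)
  expect_identical(tr0$model@weights, m@weights)
  expect_length(tr0$loss, 0)
  tr <- trainMnn(m, X, epochs = 200)
  expect_lte(utils::tail(tr$loss, 1), tr$loss[1])
})

test_that("the linear test mode matches the PCA-optimal reconstruction", {
  set.seed(3)
  Z <- matrix(rnorm(250 * 2), 250, 2) %*% matrix(rnorm(2 * 5), 2, 5) +
    matrix(rnorm(250 * 5, sd = 0.05), 250, 5)
  Z <- scale(Z, scale = FALSE)
  tr <- trainMnn(buildMnn(5, 2, seed = 4, activation = "identity"),
                 Z, epochs = 3000)
  p <- stats::prcomp(Z)
  pcaErr <- mean((Z - p$x[, 1:2] %*% t(p$rotation[, 1:2]))^2)
  expect_lt(utils::tail(tr$loss, 1), pcaErr * 1.01)
})

test_that("a 1-d bottleneck on curved data beats the best linear projection", {
  set.seed(4)
  th <- runif(400, 0, pi)
  arc <- cbind(cos(th), sin(th)) + matrix(rnorm(800, sd = 0.03), 400)
  arc <- scale(arc, scale = FALSE)
  arc <- arc / max(abs(arc))
  p <- stats::prcomp(arc)
  pcaErr <- mean((arc - p$x[, 1, drop = FALSE] %*%
                    t(p$rotation[, 1, drop = FALSE]))^2)
  tr <- trainMnn(buildMnn(2, 1, h = 10, seed = 3), arc, epochs = 3000)
  expect_lt(utils::tail(tr$loss, 1), pcaErr)
})

test_that("component extraction validates widths and maps constants", {
  m <- buildMnn(4, 2, seed = 1)
  X <- matrix(0.3, 50, 4)
  pcs <- extractNonlinearPcs(m, X)
  expect_equal(dim(pcs), c(50L, 2L))
  expect_true(all(apply(pcs, 2, function(col) diff(range(col)) == 0)))
  expect_error(extractNonlinearPcs(m, matrix(0, 5, 3)), "width")
})
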