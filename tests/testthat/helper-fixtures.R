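# Shared fixtures: everything is generated in code at test time.

# A complete synthetic session on the standard operating point:
# 8 channels, 4 sources, 256 Hz, one 7000-sample block.
makeSession <- function(seed, nBlocks = 10L, noiseSigma = 0) {
  simulateSession(nBlocks = nBlocks, duration = 7000 / 256,
                  noiseSigma = noiseSigma, seed = seed)
}

truthOf <- function(sess) list(sources = sess$sources, model = sess$model)

# 2-d rotation matrix.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

# A matrix with an exactly-identity sample covariance (rows are exactly
# whitened), handy for whitening fixed-point tests.
exactWhite <- function(N, n, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(N * n), N)
  x <- x - rowMeans(x)
  t(solve(chol(tcrossprod(x) / n))) %*% x
}

# Best-match absolute correlation between recovered and true components:
# for each true source, the highest |cor| over recovered rows.
bestMatchCor <- function(yhat, strue) {
  cc <- abs(stats::cor(t(yhat), t(strue)))
  apply(cc, 2, max)
}

# Independent brute-force evaluation of the separation performance index,
# written as explicit loops so it shares no code with the package version.
bruteForcePi <- function(C) {
  Mn <- ncol(C)
  Nn <- nrow(C)
  total <- 0
  for (i in seq_len(Nn)) {
    num <- 0; den <- 0
    for (j in seq_len(Mn)) {
      v <- abs(C[i, j])^2
      den <- den + v
      if (v > num) num <- v
    }
    total <- total + (1 - num / den)
  }
  for (i in seq_len(Mn)) {
    num <- 0; den <- 0
    for (j in seq_len(Nn)) {
      v <- abs(C[j, i])^2
      den <- den + v
      if (v > num) num <- v
    }
    total <- total + (1 - num / den)
  }
  total / (2 * (Mn - 1))
}

# Random signed permutation matrix.
randomScaledPermutation <- function(n, seed) {
  set.seed(seed)
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), sample(n))] <- runif(n, 0.2, 5) * sample(c(-1, 1), n,
                                                               replace = TRUE)
  P
}
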