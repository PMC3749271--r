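#' Initialize an adaptive-whitening state
#'
#' `P(0) = I` and learning rate `eta(0)` stored as a reciprocal accumulator.
#' The rate is self-normalizing: each update folds the block's mean squared
#' output norm into `1/eta <- (1 - xi) / eta + ||u||^2`, so the steady-state
#' rate is approximately `xi / E||u||^2` and the forgetting factor `xi` sets
#' the effective averaging window (about `1/xi` updates).
#'
#' @param N dimension of the pre-separated signal.
#' @param xi forgetting factor in (0, 1); 0.01 is the operating default.
#' @param eta0 initial learning rate.
#' @return A [WhiteningState-class].
#' @export
whiteningState <- function(N, xi = 0.01, eta0 = 0.1) {
  new("WhiteningState", P = diag(N), invEta = 1 / eta0, xi = xi,
      Ruu = diag(N), J2 = numeric(0), converged = FALSE, epochs = 0L)
}

#' One adaptive-whitening update
#'
#' Processes one signal block: computes `u = P xc`, estimates the block
#' covariance `Ruu`, advances the self-normalizing learning rate, and applies
#' `P <- P + eta (I - Ruu) P`.  The identity covariance is the fixed point:
#' for an already-white block the update vanishes up to sampling error.
#'
#' @param state a [WhiteningState-class].
#' @param block signal block, N x samples.
#' @return The updated [WhiteningState-class]; the block cost
#'   `J2 = ||Ruu - I||_F^2 / 4` is appended to its trajectory.
#' @export
whitenUpdate <- function(state, block) {
  block <- as.matrix(block)
  N <- nrow(state@P)
  stopDim(nrow(block) == N, "block dimension does not match the state")
  u <- state@P %*% block
  Ruu <- tcrossprod(u) / ncol(u)
  state@invEta <- (1 - state@xi) * state@invEta + mean(colSums(u^2))
  eta <- 1 / state@invEta
  P <- state@P + eta * (diag(N) - Ruu) %*% state@P
  if (!all(is.finite(P)))
    stop("whitening update diverged (non-finite P)", call. = FALSE)
  state@P <- P
  state@Ruu <- Ruu
  state@J2 <- c(state@J2, norm(Ruu - diag(N), "F")^2 / 4)
  state
}

#' Run adaptive whitening to convergence
#'
#' Streams the pre-separated signal through [whitenUpdate()] in blocks,
#' epoch by epoch, until the whitened full-signal covariance satisfies
#' `||Ruu - I||_F / N < tol` or `maxEpochs` is reached.
#'
#' @param xc pre-separated signal (N x samples), zero-mean.
#' @param xi forgetting factor.
#' @param eta0 initial learning rate.
#' @param blockSize covariance-estimation block length in samples (default
#'   256, i.e. one second at 256 Hz).
#' @param maxEpochs maximum passes over the signal.
#' @param tol convergence tolerance on the normalized whiteness residual.
#' @return A list with `state` (final [WhiteningState-class], `converged`
#'   flag set), `u` (the whitened signal `P xc`) and `J2` (per-block cost
#'   trajectory).
#' @export
whitenRun <- function(xc, xi = 0.01, eta0 = 0.1, blockSize = 256L,
                      maxEpochs = 50L, tol = 0.02) {
  xc <- as.matrix(xc)
  N <- nrow(xc); n <- ncol(xc)
  state <- whiteningState(N, xi = xi, eta0 = eta0)
  starts <- seq(1L, n, by = blockSize)
  for (ep in seq_len(maxEpochs)) {
    for (b in starts)
      state <- whitenUpdate(state, xc[, b:min(b + blockSize - 1L, n),
                                      drop = FALSE])
    state@epochs <- ep
    u <- state@P %*% xc
    resid <- norm(tcrossprod(u) / n - diag(N), "F") / N
    if (resid < tol) { state@converged <- TRUE; break }
  }
  list(state = state, u = state@P %*% xc, J2 = state@J2)
}
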