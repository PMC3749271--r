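#' Initialize an NPCA separation state
#'
#' `W(0) = I`, learning rate stored as a reciprocal accumulator with the same
#' self-normalizing schedule as the whitening stage
#' (`1/mu <- (1 - gamma) / mu + ||y||^2`, steady state about
#' `gamma / E||y||^2`).
#'
#' @param N signal dimension.
#' @param gamma forgetting factor in (0, 1); 0.002 is the operating default.
#' @param mu0 initial learning rate.
#' @param rule update rule: `"npca"` for the adaptive rule
#'   `W + mu f(y) (u - f(y))^T W`, or `"subspace"` for the classical
#'   `W + mu (u - W f(y)) f(y)^T`.  See Details.
#' @param orthoEvery symmetric re-orthonormalization period in samples (keeps
#'   `W^T W = I`, which the rule's derivation assumes); 0 disables.
#'
#' @details
#' Both rules use the odd nonlinearity `f(t) = tanh(t)` (the derivative of
#' `g(t) = log cosh(t)`), which injects the higher-order statistics that
#' second-order stages cannot see.  The two rules behave differently: the
#' `"npca"` rule is a stable local rule that preserves and polishes an
#' already-separated configuration (the situation after pre-separation and
#' whitening) but does not rotate an arbitrary mixture to independence on its
#' own; the `"subspace"` rule recovers rotations of sub-Gaussian sources from
#' scratch but can wander off the separating point under long streaming on
#' near-Gaussian inputs.  The pipeline therefore defaults to `"npca"`.
#'
#' @return A [SeparationState-class].
#' @export
separationState <- function(N, gamma = 0.002, mu0 = 0.1,
                            rule = c("npca", "subspace"),
                            orthoEvery = 100L) {
  rule <- match.arg(rule)
  new("SeparationState", W = diag(N), invMu = 1 / mu0, gamma = gamma,
      rule = rule, orthoEvery = as.integer(orthoEvery), counter = 0L)
}

#' One NPCA separation update
#'
#' Computes `y = W^T u`, advances the self-normalizing learning rate, applies
#' the selected update rule, and re-orthonormalizes `W` every `orthoEvery`
#' samples.  At a separated configuration the expected update is
#' diagonal-balanced, so `W` only drifts by the stochastic fluctuation of one
#' sample.
#'
#' @param state a [SeparationState-class].
#' @param u one whitened sample (length-N vector).
#' @return The updated [SeparationState-class].
#' @export
separationUpdate <- function(state, u) {
  stopDim(length(u) == nrow(state@W), "sample dimension does not match state")
  y <- drop(crossprod(state@W, u))
  f <- tanh(y)
  state@invMu <- (1 - state@gamma) * state@invMu + sum(y^2)
  mu <- 1 / state@invMu
  W <- if (state@rule == "npca") {
    state@W + mu * (f %*% t(u - f)) %*% state@W
  } else {
    state@W + mu * (u - state@W %*% f) %*% t(f)
  }
  if (!all(is.finite(W)))
    stop("separation update diverged (non-finite W); consider rule='subspace' or a larger gamma",
         call. = FALSE)
  state@counter <- state@counter + 1L
  if (state@orthoEvery > 0L && state@counter %% state@orthoEvery == 0L)
    W <- orthonormalize(W)
  state@W <- W
  state
}

# Fast internal streaming loop shared by npcaSeparate() and the pipeline.
# scoreFun(W, iter), when given, is evaluated every scoreEvery samples.
npcaStream <- function(u, W, invMu, gamma, rule, orthoEvery, passes,
                       scoreEvery = 0L, scoreFun = NULL,
                       orthTraceEvery = 100L) {
  N <- nrow(u); n <- ncol(u)
  iters <- integer(0); scores <- numeric(0)
  orthIter <- integer(0); orth <- numeric(0)
  epochScore <- numeric(0)
  kk <- 0L
  IN <- diag(N)
  for (ep in seq_len(passes)) {
    for (k in seq_len(n)) {
      uk <- u[, k]
      y <- drop(crossprod(W, uk))
      f <- tanh(y)
      invMu <- (1 - gamma) * invMu + sum(y^2)
      mu <- 1 / invMu
      W <- if (rule == "npca") W + mu * (f %*% t(uk - f)) %*% W
           else W + mu * (uk - W %*% f) %*% t(f)
      kk <- kk + 1L
      if (orthoEvery > 0L && kk %% orthoEvery == 0L) W <- orthonormalize(W)
      if (!all(is.finite(W)))
        stop("separation diverged (non-finite W)", call. = FALSE)
      if (orthTraceEvery > 0L && kk %% orthTraceEvery == 0L) {
        orthIter <- c(orthIter, kk)
        orth <- c(orth, norm(crossprod(W) - IN, "F"))
      }
      if (!is.null(scoreFun) && scoreEvery > 0L && kk %% scoreEvery == 0L) {
        iters <- c(iters, kk)
        scores <- c(scores, scoreFun(W, kk))
      }
    }
    if (!is.null(scoreFun)) epochScore <- c(epochScore, scoreFun(W, kk))
  }
  list(W = W, invMu = invMu, iters = iters, scores = scores,
       orthTrace = data.frame(iteration = orthIter, offOrth = orth),
       epochScore = epochScore)
}

#' NPCA separation of a whitened signal
#'
#' Streams all samples of `u` through [separationUpdate()] `passes` times and
#' returns the final separation matrix, the separated signal `y = W^T u`, and
#' the trace of the orthogonality residual `||W^T W - I||_F`.
#'
#' @param u whitened signal (N x samples, `Ruu` close to the identity).
#' @param gamma forgetting factor.
#' @param passes passes over the signal.
#' @param mu0 initial learning rate.
#' @param rule,orthoEvery see [separationState()].
#' @return A list with `state` (final [SeparationState-class]), `y`
#'   (separated N x samples signal) and `orthTrace` (data.frame of
#'   `iteration`, `offOrth`).
#' @examples
#' # two whitened uniform sources mixed by a rotation
#' set.seed(1)
#' S <- matrix(runif(2 * 2000, -sqrt(3), sqrt(3)), 2)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
#' out <- npcaSeparate(R %*% S, passes = 5, rule = "subspace")
#' abs(cor(t(out$y), t(S)))
#' @export
npcaSeparate <- function(u, gamma = 0.002, passes = 1L, mu0 = 0.1,
                         rule = c("npca", "subspace"), orthoEvery = 100L) {
  rule <- match.arg(rule)
  u <- as.matrix(u)
  st <- separationState(nrow(u), gamma = gamma, mu0 = mu0, rule = rule,
                        orthoEvery = orthoEvery)
  res <- npcaStream(u, st@W, st@invMu, gamma, rule, as.integer(orthoEvery),
                    as.integer(passes))
  st@W <- res$W
  st@invMu <- res$invMu
  st@counter <- as.integer(passes) * ncol(u)
  list(state = st, y = t(res$W) %*% u, orthTrace = res$orthTrace)
}
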