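#' Spatial whitening by eigendecomposition
#'
#' First half of the pre-separation stage: eigendecomposes the sample sensor
#' covariance and projects onto the `nKeep` largest eigenvalues, scaling each
#' retained component to unit variance (`B = Lambda^{-1/2} V^T`).
#'
#' The automatic component-count rule looks for the largest gap (in decades)
#' of the descending eigenvalue spectrum: when some eigenvalue drops by two or
#' more orders of magnitude relative to its predecessor, the spectrum above
#' the gap is kept.  Without a clear gap, eigenvalues above `1e-3` of the
#' largest are kept.  This retains weak but genuine sources (the P300
#' component carries orders of magnitude less variance than the background)
#' while discarding the numerical null space of a rank-deficient mixture.
#'
#' @param rec a [Recording-class] or a channels x samples matrix (needs at
#'   least `2 * M` samples).
#' @param nKeep number of components to keep, or `"auto"`.
#' @return A list with `state` (a [PreSeparationState-class] with `B`,
#'   `eigenvalues`, `V` filled in) and `xbar`, the whitened N x samples matrix.
#' @export
spatialWhiten <- function(rec, nKeep = "auto") {
  X <- if (is(rec, "Recording")) recData(rec) else as.matrix(rec)
  M <- nrow(X)
  stopDim(ncol(X) >= 2 * M, "at least 2*M samples are required")
  X <- X - rowMeans(X)
  e <- symEigen(tcrossprod(X) / ncol(X))
  lam <- pmax(e$values, 0)
  rank <- sum(lam > lam[1] * 1e-12)
  if (identical(nKeep, "auto")) {
    lamPos <- pmax(lam, lam[1] * 1e-15)
    gaps <- diff(log10(lamPos))        # negative steps, length M-1
    k <- which.min(gaps)               # largest drop
    nKeep <- if (gaps[k] <= -2) k else sum(lam > lam[1] * 1e-3)
  }
  if (nKeep > rank)
    stop("dimension error: nKeep exceeds the numerical rank of the covariance",
         call. = FALSE)
  B <- diag(1 / sqrt(lam[seq_len(nKeep)]), nKeep) %*%
    t(e$vectors[, seq_len(nKeep), drop = FALSE])
  state <- new("PreSeparationState", B = B, eigenvalues = lam,
               V = e$vectors, rotation = diag(nKeep), d = numeric(0),
               tau = 1L, Ahat = matrix(0, M, nKeep), degenerate = FALSE)
  list(state = state, xbar = B %*% X)
}

#' Delayed-covariance rotation
#'
#' Second half of the pre-separation stage.  For each delay `tau` the signal
#' `xtilde(k) = xbar(k) + xbar(k - tau)` has covariance
#' `2 R(0) + R(tau) + R(tau)^T`; for whitened mixtures of temporally colored,
#' mutually uncorrelated sources this matrix is diagonalized by the (orthogonal)
#' residual mixing, with diagonal entries `2 (1 + E s_i(k) s_i(k-tau))`.  Its
#' eigendecomposition therefore recovers the rotation whenever those lagged
#' autocorrelations are distinct.  Supplying several delays averages the
#' delayed covariances before the eigendecomposition, which stabilizes the
#' rotation when no single lag separates all source pairs.
#'
#' @param xbar whitened signal (N x samples) from [spatialWhiten()].
#' @param tau integer delay(s) in samples, each >= 1.
#' @param state optional [PreSeparationState-class] from [spatialWhiten()];
#'   when given, the rotation, delayed-covariance spectrum and the stage-1
#'   mixing estimate `B^+ V` are recorded in it.
#' @param gapTol relative eigenvalue-gap threshold below which the rotation is
#'   flagged as degenerate (non-unique).
#' @return A list with `state` (updated, or a fresh state when none given),
#'   `xc` (the pre-separated signal `V^T xbar`), `d` (delayed-covariance
#'   eigenvalues) and `degenerate`.
#' @export
delayedRotation <- function(xbar, tau = 1:5, state = NULL, gapTol = 1e-3) {
  xbar <- as.matrix(xbar)
  if (any(tau < 1)) stop("tau must be >= 1 sample", call. = FALSE)
  N <- nrow(xbar); n <- ncol(xbar)
  Rsum <- matrix(0, N, N)
  for (tk in as.integer(tau)) {
    a <- xbar[, (tk + 1):n, drop = FALSE]
    b <- xbar[, 1:(n - tk), drop = FALSE]
    R0 <- tcrossprod(a) / (n - tk)
    Rt <- a %*% t(b) / (n - tk)
    Rsum <- Rsum + 2 * R0 + Rt + t(Rt)
  }
  Rsum <- Rsum / length(tau)
  e <- symEigen(Rsum)
  gaps <- abs(diff(e$values))
  degenerate <- N > 1 && any(gaps < gapTol * mean(abs(e$values)))
  if (degenerate)
    warning("near-degenerate delayed-covariance eigenvalues: rotation is not unique",
            call. = FALSE)
  xc <- t(e$vectors) %*% xbar
  if (is.null(state)) {
    state <- new("PreSeparationState", B = diag(N),
                 eigenvalues = numeric(0), V = diag(N),
                 rotation = e$vectors, d = e$values,
                 tau = as.integer(tau), Ahat = e$vectors,
                 degenerate = degenerate)
  } else {
    state@rotation <- e$vectors
    state@d <- e$values
    state@tau <- as.integer(tau)
    state@degenerate <- degenerate
    # B^+ = V_j Lambda_j^{1/2}: the pseudo-inverse of the whitening map
    k <- nrow(state@B)
    state@Ahat <- state@V[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(state@eigenvalues[seq_len(k)]), k) %*% e$vectors
  }
  list(state = state, xc = xc, d = e$values, degenerate = degenerate)
}

#' Run the complete pre-separation stage
#'
#' [spatialWhiten()] followed by [delayedRotation()].  The total stage
#' transform is `t(rotation) %*% B`, available via [preSeparationTransform()].
#'
#' @inheritParams spatialWhiten
#' @inheritParams delayedRotation
#' @return A list with `state` (a fully populated
#'   [PreSeparationState-class]) and `xc`, the pre-separated signal.
#' @examples
#' sess <- simulateSession(nBlocks = 4, seed = 2)
#' ps <- preSeparate(sess$recording, nKeep = 4)
#' dim(ps$xc)
#' @export
preSeparate <- function(rec, tau = 1:5, nKeep = "auto", gapTol = 1e-3) {
  sw <- spatialWhiten(rec, nKeep = nKeep)
  dr <- delayedRotation(sw$xbar, tau = tau, state = sw$state, gapTol = gapTol)
  list(state = dr$state, xc = dr$xc)
}

#' Total pre-separation transform
#'
#' The matrix `V = t(rotation) %*% B` mapping sensor signals to the
#' pre-separated components; this is the `V` factor of the combined system
#' `C = W^T P V`.
#'
#' @param state a [PreSeparationState-class].
#' @return N x M matrix.
#' @export
preSeparationTransform <- function(state) t(state@rotation) %*% state@B

#' Reconstruction cost of a tracked principal-component vector
#'
#' For the online tracker, the per-sample cost is the squared norm of the
#' reconstruction error `e = x - v (v^T x)`, i.e.
#' `E(v) = ||(I - v v^T) x||^2 / 2` for real signals.
#'
#' @param v candidate component vector.
#' @param x one signal sample (vector).
#' @return Scalar cost.
#' @seealso [pcGrad()], [trackPC()]
#' @export
pcCost <- function(v, x) {
  e <- x - v * sum(v * x)
  sum(e^2) / 2
}

#' Analytic gradient of the tracking cost
#'
#' Gradient of [pcCost()] with respect to `v`:
#' `dE/dv = -c (2 - ||v||^2) x + c^2 v` with `c = v^T x`.  The online update
#' of [trackPC()] follows the negative of this gradient; the simplified
#' one-term rule drops the second term, which vanishes as `||v|| -> 1`.
#'
#' @inheritParams pcCost
#' @return Gradient vector.
#' @export
pcGrad <- function(v, x) {
  cc <- sum(v * x)
  -cc * (2 - sum(v^2)) * x + cc^2 * v
}

#' Online principal-component tracking
#'
#' Streams samples through the stochastic-gradient update
#' `v <- v + beta * c * (x - v c)` with `c = v^T x` (the real-valued
#' specialization of the complex rule; conjugates are identities on real
#' EEG).  At the dominant eigenvector of a stationary stream the update is
#' zero in expectation and `||v||` is driven to 1.
#'
#' @param x signal matrix (components x samples), streamed column by column.
#' @param beta learning rate (> 0); 0.6 is the operating default of the
#'   pre-separation stage.
#' @param v0 initial vector (nonzero); defaults to a small random vector.
#' @param deflate optional matrix whose columns are previously extracted
#'   components; the stream is projected onto their orthogonal complement
#'   first, so the tracker converges to the next component in the hierarchy.
#' @param passes passes over the data.
#' @param maxNorm divergence guard; the tracker halts with an error when
#'   `||v||` exceeds it.
#' @return A list with `v` (final vector), `cost` (per-step cost trajectory)
#'   and `norms` (per-step `||v||`).
#' @export
trackPC <- function(x, beta = 0.6, v0 = NULL, deflate = NULL, passes = 1L,
                    maxNorm = 10) {
  x <- as.matrix(x)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (!is.null(deflate)) {
    D <- as.matrix(deflate)
    x <- x - D %*% (t(D) %*% x)
  }
  v <- v0 %||% withSeed(1L, rnorm(nrow(x), sd = 0.1))
  if (all(v == 0)) stop("v0 must be nonzero", call. = FALSE)
  nsteps <- ncol(x) * passes
  cost <- numeric(nsteps); norms <- numeric(nsteps)
  step <- 0L
  for (p in seq_len(passes)) for (k in seq_len(ncol(x))) {
    xk <- x[, k]
    cc <- sum(v * xk)
    v <- v + beta * cc * (xk - v * cc)
    step <- step + 1L
    cost[step] <- pcCost(v, xk)
    norms[step] <- sqrt(sum(v^2))
    if (norms[step] > maxNorm)
      stop("tracker diverged (||v|| > ", maxNorm,
           "); try a smaller learning rate beta", call. = FALSE)
  }
  list(v = v, cost = cost, norms = norms)
}
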