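#' Stochastic mixing-matrix estimation
#'
#' Fourth ANPCA stage: re-estimates the mixing matrix from the separated
#' signal by the stochastic rule `Q <- Q + alpha (x - Q y) y^T`, starting from
#' `Q(0) = 0`.  At convergence `Q` minimizes the reconstruction residual
#' `||x - Q y||`, so its columns estimate the mixing columns (up to the
#' permutation/scale indeterminacy of `y`).
#'
#' @param y separated signal (N x samples).
#' @param xTarget signal to reconstruct (M x samples), sample-aligned with
#'   `y`.
#' @param alpha learning rate (default 0.3).
#' @param epochs passes over the data.
#' @return An [EstimationState-class] with the final `Q`.
#' @export
estimateMixing <- function(y, xTarget, alpha = 0.3, epochs = 1L) {
  y <- as.matrix(y); xTarget <- as.matrix(xTarget)
  stopDim(ncol(y) == ncol(xTarget), "y and xTarget must be sample-aligned")
  Q <- matrix(0, nrow(xTarget), nrow(y))
  for (ep in seq_len(epochs)) for (k in seq_len(ncol(y))) {
    yk <- y[, k]
    Qe <- xTarget[, k] - Q %*% yk
    Q <- Q + alpha * Qe %*% t(yk)
    if (!all(is.finite(Q)))
      stop("mixing estimation diverged (non-finite Q); reduce alpha",
           call. = FALSE)
  }
  new("EstimationState", Q = Q, alpha = alpha)
}

#' Combined unmixing system
#'
#' The product `C = W P V` of the three learned transforms, where `W` is the
#' separation matrix as applied (`y = W^T u`, so pass `t(W)` of the stored
#' state, or use the convenience in [runPipeline()]), `P` the whitening
#' matrix and `V` the total pre-separation transform
#' ([preSeparationTransform()]).  In the zero-forcing limit `C A` approaches a
#' scaled permutation.
#'
#' @param W,P,V conformable matrices.
#' @return The matrix product `W %*% P %*% V`.
#' @export
combinedSystem <- function(W, P, V) {
  stopDim(ncol(W) == nrow(P) && ncol(P) == nrow(V),
          "input error: non-conformable dimensions")
  W %*% P %*% V
}

#' Separation performance index
#'
#' For a combined system `C` (rows = outputs, columns = sources) the index
#' averages, over rows and over columns, one minus the energy fraction of the
#' dominant entry:
#' `PI = (1 / (2 (M - 1))) * sum_i [(1 - Ca_i) + (1 - Cb_i)]` with
#' `Ca_i = max_j c_ij^2 / sum_j c_ij^2` (rows) and
#' `Cb_i = max_j c_ji^2 / sum_j c_ji^2` (columns), `M = ncol(C)`.
#' `PI` is 0 exactly when `C` is a scaled permutation (perfect separation)
#' and 1 for an all-equal square matrix (maximal mixing).
#'
#' The index is meaningful on the global source-to-output transfer expressed
#' for unit-variance sources; when scoring against a known mixture, pass
#' `C %*% A %*% diag(apply(S, 1, sd))` (see [pipelinePi()]).
#'
#' @param C a nonzero matrix with no all-zero row or column and
#'   `nrow(C) <= ncol(C)`.
#' @return PI in \[0, 1\].
#' @examples
#' performanceIndex(diag(3)[, c(2, 3, 1)] * c(2, -1, 0.5))  # 0
#' performanceIndex(matrix(1, 4, 4))                        # 1
#' @export
performanceIndex <- function(C) {
  C <- as.matrix(C)
  C2 <- C^2
  rs <- rowSums(C2); cs <- colSums(C2)
  if (all(C2 == 0) || any(rs == 0) || any(cs == 0))
    stop("input error: C has an all-zero row or column", call. = FALSE)
  Mn <- ncol(C2)
  Ca <- apply(C2, 1, max) / rs
  Cb <- apply(C2, 2, max) / cs
  (sum(1 - Ca) + sum(1 - Cb)) / (2 * (Mn - 1))
}

#' Performance index in decibels
#'
#' `20 log10(PI)`: the convention consistent with the linear index (0.03
#' corresponds to about -30 dB).
#'
#' @param pi_ performance index in (0, 1\].
#' @return Decibel value; `-Inf` for `pi_ = 0`.
#' @export
piDb <- function(pi_) {
  if (any(pi_ < 0)) stop("PI must be non-negative", call. = FALSE)
  ifelse(pi_ == 0, -Inf, 20 * log10(pi_))
}

#' Detect the convergence epoch of a PI trajectory
#'
#' Returns the first epoch `e` whose relative change
#' `|PI(e+1) - PI(e)| / PI(e)` stays below `tol` for two consecutive epoch
#' transitions (one transition suffices at the end of the trajectory).  A flat
#' trajectory converges at epoch 1.
#'
#' @param piTrajectory numeric vector of per-epoch PI values (length >= 2).
#' @param tol relative-change tolerance (default 0.01).
#' @return A list with `epoch` (integer, `NA` when never converged) and
#'   `converged` (logical).
#' @export
convergenceEpochs <- function(piTrajectory, tol = 0.01) {
  p <- as.numeric(piTrajectory)
  if (length(p) < 2) stop("at least 2 epochs are required", call. = FALSE)
  rc <- abs(diff(p)) / pmax(utils::head(p, -1), .Machine$double.eps)
  ok <- rc < tol
  sustained <- ok & c(ok[-1], TRUE)
  e <- which(sustained)
  if (length(e)) list(epoch = as.integer(e[1]), converged = TRUE)
  else list(epoch = NA_integer_, converged = FALSE)
}

#' Block-wise target classification from ERP epochs
#'
#' For each block, each stimulus is scored by the mean amplitude of its epoch
#' in the scoring window (250-450 ms by default, bracketing the P300 peak),
#' optionally averaging each stimulus' epochs over the last `m` blocks; the
#' predicted target is the highest-scoring stimulus.  Accuracy is the
#' fraction of blocks whose prediction matches the session target, and is
#' also reported for every averaging depth `m = 1 .. nBlocks`.
#'
#' @param epochs an [EpochSet-class] extracted from the separated ERP
#'   component (single channel, or channels are averaged).
#' @param events schedule; defaults to the one stored in `epochs`.
#' @param scoreWindow numeric(2), scoring window in seconds relative to
#'   onset.
#' @param m default averaging depth (blocks), 3 by default.
#' @param channel channel index to score, or `NULL` to average channels.
#' @return A [ClassificationResult-class].
#' @export
classifyBlocks <- function(epochs, events = epochs@events,
                           scoreWindow = c(0.25, 0.45), m = 3L,
                           channel = NULL) {
  blocks <- sort(unique(blockIds(events)))
  if (length(blocks) < 1) stop("input error: at least one block is required",
                               call. = FALSE)
  tt <- epochTimes(epochs)
  sel <- which(tt >= scoreWindow[1] & tt <= scoreWindow[2])
  if (!length(sel)) stop("scoring window outside the epoch window",
                         call. = FALSE)
  dat <- epochData(epochs)
  chan <- if (is.null(channel)) seq_len(dim(dat)[2]) else channel
  # per-event scalar score: mean amplitude over channels and window
  ev <- apply(dat[, chan, sel, drop = FALSE], 1, mean)
  stim <- stimulusIds(events)
  blk <- blockIds(events)
  nStim <- max(stim)
  scoreMat <- matrix(NA_real_, length(blocks), nStim)  # block x stimulus
  for (bi in seq_along(blocks)) for (s in seq_len(nStim))
    scoreMat[bi, s] <- mean(ev[blk == blocks[bi] & stim == s])
  predictAt <- function(mm) {
    vapply(seq_along(blocks), function(bi) {
      lo <- max(1L, bi - mm + 1L)
      which.max(colMeans(scoreMat[lo:bi, , drop = FALSE]))
    }, integer(1))
  }
  accByM <- data.frame(m = seq_along(blocks), accuracy = vapply(
    seq_along(blocks),
    function(mm) mean(predictAt(mm) == targetId(events)), numeric(1)))
  mUse <- min(m, length(blocks))
  pred <- predictAt(mUse)
  new("ClassificationResult", predicted = as.integer(pred),
      truth = targetId(events), accuracy = mean(pred == targetId(events)),
      accuracyByM = accByM, scoreWindow = scoreWindow, m = as.integer(mUse))
}
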