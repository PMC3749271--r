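#' @import methods
#' @importFrom stats approx cor rnorm runif sd var
NULL

#' Oddball stimulus schedule
#'
#' An `EventSequence` holds the stimulus schedule of an oddball session:
#' onset times, stimulus identities, block membership, and the identity of the
#' attended (target) stimulus.  In each block every stimulus is flashed exactly
#' once, in random order; consecutive onsets are one inter-stimulus interval
#' (ISI) apart, the ISI being the flash duration plus a 300 ms blank.
#'
#' @slot onsets numeric, strictly increasing onset times in seconds.
#' @slot stimulus integer, stimulus identity (1..nStimuli) per event.
#' @slot block integer, zero-based block index per event.
#' @slot targetId integer(1), the attended stimulus identity (constant for the
#'   session).
#' @slot flashDuration numeric(1), flash duration in seconds.
#' @slot isi numeric(1), onset-to-onset interval in seconds.
#'
#' @seealso [generateStimulusSequence()]
#' @export
setClass("EventSequence",
  representation(onsets = "numeric", stimulus = "integer", block = "integer",
                 targetId = "integer", flashDuration = "numeric",
                 isi = "numeric"))

setValidity("EventSequence", function(object) {
  msg <- character()
  n <- length(object@onsets)
  if (length(object@stimulus) != n || length(object@block) != n)
    msg <- c(msg, "onsets, stimulus and block must have equal length")
  if (n > 1) {
    d <- diff(object@onsets)
    if (any(d <= 0)) msg <- c(msg, "onsets must be strictly increasing")
    if (any(abs(d - object@isi) > 0.5 / 256 + 1e-9))
      msg <- c(msg, "consecutive onsets must be one ISI apart (within half a sample at 256 Hz)")
  }
  if (abs(object@flashDuration + 0.300 - object@isi) > 1e-3)
    msg <- c(msg, "flashDuration + 0.300 s must equal the ISI (within 1 ms)")
  if (n > 0) {
    for (b in unique(object@block)) {
      st <- sort(object@stimulus[object@block == b])
      if (!identical(st, seq_along(st)))
        msg <- c(msg, sprintf("block %d does not contain each stimulus exactly once", b))
    }
    if (!(object@targetId %in% object@stimulus))
      msg <- c(msg, "targetId must be one of the stimulus identities")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth source signals
#'
#' A `SourceSet` is an N x samples matrix of source waveforms (in microvolts)
#' with one kind label per row: `"erp"` (the P300-like component), `"background"`
#' (colored ongoing activity) or `"artifact"` (slow ramps).  Rows are zero-mean
#' and mutually uncorrelated over the generated window.
#'
#' @slot S numeric matrix, sources x samples, in microvolts.
#' @slot kinds character, one of `"erp"`, `"background"`, `"artifact"` per row.
#' @slot fs numeric(1), sampling rate in Hz.
#'
#' @seealso [generateSources()]
#' @export
setClass("SourceSet",
  representation(S = "matrix", kinds = "character", fs = "numeric"))

setValidity("SourceSet", function(object) {
  msg <- character()
  if (nrow(object@S) < 1) msg <- c(msg, "at least one source is required")
  if (length(object@kinds) != nrow(object@S))
    msg <- c(msg, "one kind label per source row is required")
  if (!all(object@kinds %in% c("erp", "background", "artifact")))
    msg <- c(msg, "kinds must be 'erp', 'background' or 'artifact'")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  rms <- sqrt(rowMeans(object@S^2))
  off <- abs(rowMeans(object@S))
  if (any(rms > 0 & off > 1e-6 * pmax(rms, 1e-12)))
    msg <- c(msg, "source rows must be zero-mean (within 1e-6 of their RMS)")
  if (length(msg)) msg else TRUE
})

#' Linear instantaneous mixing model
#'
#' Sensor signals are modeled as `x(k) = A s(k) + n(k)`: a full-column-rank
#' M x N mixing matrix applied to N sources plus i.i.d. Gaussian sensor noise.
#'
#' @slot A numeric matrix, M x N, full column rank, unit-norm columns.
#' @slot noiseSigma numeric(1), sensor noise standard deviation in microvolts.
#' @slot seed integer(1), the seed the matrix was drawn with.
#'
#' @seealso [makeMixing()], [mixSources()]
#' @export
setClass("MixtureModel",
  representation(A = "matrix", noiseSigma = "numeric", seed = "integer"))

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (nrow(object@A) < ncol(object@A))
    msg <- c(msg, "mixing matrix must have at least as many rows (channels) as columns (sources)")
  if (qr(object@A)$rank < ncol(object@A))
    msg <- c(msg, "mixing matrix must have full column rank")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Multichannel recording
#'
#' A `Recording` is a channels x samples potential matrix (microvolts) with a
#' sampling rate and channel labels.  The default eight-channel montage is
#' Fz, Cz, Pz, Oz, P7, P3, P4, P8.
#'
#' @slot X numeric matrix, channels x samples, in microvolts.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot channelLabels character, one label per channel.
#'
#' @seealso [mixSources()], [readRecording()]
#' @export
setClass("Recording",
  representation(X = "matrix", fs = "numeric", channelLabels = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (!all(is.finite(object@X))) msg <- c(msg, "all sample values must be finite")
  if (length(object@channelLabels) != nrow(object@X))
    msg <- c(msg, "label count must equal the channel count")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Band-pass filter specification
#'
#' Describes the pre-processing band-pass: a Butterworth design of even overall
#' order (default 6) with 1 and 12 Hz corner frequencies.
#'
#' @slot order integer(1), overall band-pass order (even, >= 2).
#' @slot lowHz numeric(1), lower corner frequency in Hz.
#' @slot highHz numeric(1), upper corner frequency in Hz.
#' @slot design character(1), filter family; only `"butterworth"` is provided.
#'
#' @seealso [filterSpec()], [bandpassFilter()]
#' @export
setClass("FilterSpec",
  representation(order = "integer", lowHz = "numeric", highHz = "numeric",
                 design = "character"))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (object@order < 2 || object@order %% 2 != 0)
    msg <- c(msg, "order must be even and >= 2")
  if (!(object@lowHz > 0 && object@lowHz < object@highHz))
    msg <- c(msg, "corner frequencies must satisfy 0 < lowHz < highHz")
  if (!identical(object@design, "butterworth"))
    msg <- c(msg, "only the Butterworth design is available")
  if (length(msg)) msg else TRUE
})

#' Stimulus-locked epochs
#'
#' An `EpochSet` is an events x channels x samples array of stimulus-locked,
#' baseline-corrected windows cut from a recording, together with the schedule
#' they were cut against.
#'
#' @slot data numeric array, events x channels x window samples.
#' @slot window numeric(2), window limits in seconds relative to onset
#'   (closed at both ends).
#' @slot baseline numeric(2), the interval whose mean was subtracted.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot events the [EventSequence-class] the epochs were extracted for.
#'
#' @seealso [extractEpochs()], [classifyBlocks()]
#' @export
setClass("EpochSet",
  representation(data = "array", window = "numeric", baseline = "numeric",
                 fs = "numeric", events = "EventSequence"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3-d array (events x channels x samples)")
  if (dim(object@data)[1] != length(object@events@onsets))
    msg <- c(msg, "epoch count must match the event count")
  if (length(msg)) msg else TRUE
})

#' Pre-separation state (multi-stage PCA)
#'
#' Holds the learned transforms of the first ANPCA stage: the spatial-whitening
#' matrix `B = Lambda^{-1/2} V^T` built from the largest eigenvalues of the
#' sensor covariance, and the rotation obtained from the eigendecomposition of
#' the delayed covariance of `xbar(k) + xbar(k - tau)`.
#'
#' @slot B numeric matrix, N x M spatial-whitening matrix.
#' @slot eigenvalues numeric, all sensor-covariance eigenvalues (descending).
#' @slot V numeric matrix, sensor-covariance eigenvectors (columns).
#' @slot rotation numeric matrix, eigenvectors of the delayed covariance
#'   (the rotation `V_xtilde`; the pre-separated signal is `t(rotation) %*% xbar`).
#' @slot d numeric, eigenvalues of the (lag-averaged) delayed covariance.
#' @slot tau integer, the delay (or delays, averaged) in samples.
#' @slot Ahat numeric matrix, the stage-1 mixing estimate `B^+ V_xtilde`.
#' @slot degenerate logical(1), TRUE when near-equal delayed-covariance
#'   eigenvalues make the rotation non-unique.
#'
#' @seealso [preSeparate()], [spatialWhiten()], [delayedRotation()]
#' @export
setClass("PreSeparationState",
  representation(B = "matrix", eigenvalues = "numeric", V = "matrix",
                 rotation = "matrix", d = "numeric", tau = "integer",
                 Ahat = "matrix", degenerate = "logical"))

#' Adaptive-whitening state
#'
#' State of the second ANPCA stage: the whitening matrix `P`, the
#' self-normalizing learning rate (stored as its reciprocal accumulator), the
#' forgetting factor, and the running covariance estimate of the whitened
#' output.
#'
#' @slot P numeric matrix, N x N whitening matrix.
#' @slot invEta numeric(1), reciprocal of the current learning rate.
#' @slot xi numeric(1), forgetting factor in (0, 1).
#' @slot Ruu numeric matrix, last block covariance estimate of `u = P xc`.
#' @slot J2 numeric, trajectory of the whiteness cost `||Ruu - I||_F^2 / 4`.
#' @slot converged logical(1).
#' @slot epochs integer(1), epochs actually run.
#'
#' @seealso [whitenRun()], [whitenUpdate()]
#' @export
setClass("WhiteningState",
  representation(P = "matrix", invEta = "numeric", xi = "numeric",
                 Ruu = "matrix", J2 = "numeric", converged = "logical",
                 epochs = "integer"))

#' NPCA separation state
#'
#' State of the third ANPCA stage: the separation matrix `W` (applied as
#' `y = W^T u`), the self-normalizing learning rate accumulator, the forgetting
#' factor, the update rule in use, and the orthonormalization cadence.
#'
#' @slot W numeric matrix, N x N separation matrix.
#' @slot invMu numeric(1), reciprocal of the current learning rate.
#' @slot gamma numeric(1), forgetting factor in (0, 1).
#' @slot rule character(1), `"npca"` (the adaptive rule
#'   `W + mu f(y) (u - f(y))^T W`) or `"subspace"` (the classical rule
#'   `W + mu (u - W f(y)) f(y)^T`).
#' @slot orthoEvery integer(1), symmetric re-orthonormalization period in
#'   samples (0 disables).
#' @slot counter integer(1), samples processed so far.
#'
#' @seealso [npcaSeparate()], [separationUpdate()]
#' @export
setClass("SeparationState",
  representation(W = "matrix", invMu = "numeric", gamma = "numeric",
                 rule = "character", orthoEvery = "integer",
                 counter = "integer"))

#' Mixing-estimation state
#'
#' State of the fourth ANPCA stage: the stochastically re-estimated mixing
#' matrix `Q` (the estimate of `A`) and its learning rate.
#'
#' @slot Q numeric matrix, M x N estimated mixing matrix.
#' @slot alpha numeric(1), learning rate.
#'
#' @seealso [estimateMixing()]
#' @export
setClass("EstimationState",
  representation(Q = "matrix", alpha = "numeric"))

#' Separation quality report
#'
#' The combined system `C = W^T P V` (with `V` the total pre-separation
#' transform), its separation performance index (PI) against the ground-truth
#' mixing, the PI trajectory over update iterations and over epochs, and the
#' detected convergence epoch.
#'
#' @slot C numeric matrix, the combined unmixing system.
#' @slot PI numeric(1), final performance index in \[0, 1\].
#' @slot PIdb numeric(1), `20 log10(PI)` in decibels.
#' @slot piTrajectory data.frame with columns `iteration` and `pi`.
#' @slot epochPi numeric, PI at the end of each epoch.
#' @slot convergedEpoch integer(1), first epoch with a sustained relative PI
#'   change below tolerance (NA when never reached).
#' @slot converged logical(1).
#'
#' @seealso [runPipeline()], [performanceIndex()], [convergenceEpochs()]
#' @export
setClass("QualityReport",
  representation(C = "matrix", PI = "numeric", PIdb = "numeric",
                 piTrajectory = "data.frame", epochPi = "numeric",
                 convergedEpoch = "integer", converged = "logical"))

#' Block-wise target classification result
#'
#' Per-block target predictions from stimulus-locked epochs of the separated
#' P300 component, with accuracy also reported as a function of the number of
#' averaged blocks.
#'
#' @slot predicted integer, predicted target identity per block.
#' @slot truth integer(1), the session's true target identity.
#' @slot accuracy numeric(1), fraction of blocks predicted correctly at the
#'   default averaging depth.
#' @slot accuracyByM data.frame with columns `m` (blocks averaged) and
#'   `accuracy`.
#' @slot scoreWindow numeric(2), scoring window in seconds relative to onset.
#' @slot m integer(1), averaging depth used for `predicted` and `accuracy`.
#'
#' @seealso [classifyBlocks()]
#' @export
setClass("ClassificationResult",
  representation(predicted = "integer", truth = "integer",
                 accuracy = "numeric", accuracyByM = "data.frame",
                 scoreWindow = "numeric", m = "integer"))

#' Baseline separation result
#'
#' Result of a reference separation algorithm (SOBI or plain NPCA): the total
#' unmixing transform, the PI-versus-iteration curve (iterations counted as
#' samples processed), and iterations needed to reach PI thresholds.
#'
#' @slot algorithm character(1).
#' @slot W numeric matrix, total unmixing transform (applied to channels).
#' @slot piCurve data.frame with columns `iteration` and `pi`.
#' @slot iterationsToThreshold named numeric, samples processed until
#'   PI < 0.1 and PI < 0.05 (NA when never reached).
#'
#' @seealso [sobi()], [plainNpca()], [compareAlgorithms()]
#' @export
setClass("BaselineResult",
  representation(algorithm = "character", W = "matrix",
                 piCurve = "data.frame", iterationsToThreshold = "numeric"))

#' Five-layer autoencoder for nonlinear principal components
#'
#' A multilayer neural network with layer widths (N, h, M, h, N) and
#' activations (sigmoid, linear, sigmoid, linear), trained by back-propagation
#' with momentum and an adaptive learning rate; the bottleneck activations are
#' the nonlinear principal components of the input.
#'
#' @slot sizes integer, the five layer widths.
#' @slot weights list of 4 weight matrices.
#' @slot biases list of 4 bias vectors.
#' @slot activation character(1), `"sigmoid"` or `"identity"` (linear test
#'   mode).
#' @slot learningRate numeric(1).
#' @slot momentum numeric(1).
#' @slot velocity list, momentum buffers (same shapes as weights/biases).
#'
#' @seealso [buildMnn()], [trainMnn()], [extractNonlinearPcs()]
#' @export
setClass("MnnModel",
  representation(sizes = "integer", weights = "list", biases = "list",
                 activation = "character", learningRate = "numeric",
                 momentum = "numeric", velocity = "list"))

setValidity("MnnModel", function(object) {
  msg <- character()
  s <- object@sizes
  if (length(s) != 5) msg <- c(msg, "five layer widths are required")
  else {
    if (s[1] != s[5]) msg <- c(msg, "input and output layers must have the same width")
    if (s[3] >= s[1]) msg <- c(msg, "bottleneck width must be smaller than the input width")
  }
  if (length(msg)) msg else TRUE
})
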