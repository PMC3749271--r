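#' Generate an oddball stimulus schedule
#'
#' Builds the stimulus schedule of a seven-choice oddball session: in each
#' block the `nStimuli` images flash once each, in a seeded random order, with
#' a fixed onset-to-onset interval (ISI).  The ISI is the flash duration plus a
#' 300 ms blank screen; the supported ISIs are 325, 350, 375 and 400 ms.  One
#' stimulus identity is drawn per session as the attended target and is the
#' same in every block.
#'
#' @param nBlocks number of blocks (>= 0).
#' @param isi onset-to-onset interval in seconds, in \[0.3, 0.5\].
#' @param flashDuration flash duration in seconds; must satisfy
#'   `flashDuration + 0.300 == isi` within 1 ms.
#' @param seed integer seed; all randomness (stimulus orders and target
#'   choice) flows through it.
#' @param nStimuli number of distinct stimuli per block.
#' @param firstOnset onset time of the first event in seconds.
#'
#' @return An [EventSequence-class].
#' @examples
#' ev <- generateStimulusSequence(3, isi = 0.350, seed = 1)
#' table(isTarget(ev))
#' @export
generateStimulusSequence <- function(nBlocks, isi = 0.350,
                                     flashDuration = isi - 0.300,
                                     seed = 1L, nStimuli = 7L,
                                     firstOnset = 0) {
  if (nBlocks < 0) stop("nBlocks must be >= 0", call. = FALSE)
  if (isi < 0.3 || isi > 0.5)
    stop("isi must lie in [0.3, 0.5] s", call. = FALSE)
  if (abs(flashDuration + 0.300 - isi) > 1e-3)
    stop("inconsistent schedule: flashDuration + 0.300 s must equal isi (within 1 ms)",
         call. = FALSE)
  withSeed(seed, {
    target <- sample.int(nStimuli, 1L)
    stim <- unlist(lapply(seq_len(nBlocks), function(b) sample.int(nStimuli)))
    n <- nStimuli * nBlocks
    new("EventSequence",
        onsets = firstOnset + (seq_len(n) - 1) * isi,
        stimulus = as.integer(stim %||% integer(0)),
        block = rep(seq_len(max(nBlocks, 1L)) - 1L, each = nStimuli)[seq_len(n)],
        targetId = as.integer(target),
        flashDuration = flashDuration, isi = isi)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Source-model parameters for the synthetic ERP generator
#'
#' Collects the waveform parameters of the synthetic source family.  The
#' P300-like component is a positive Gaussian bump peaking 300 ms after each
#' target onset (1.5 uV peak, 60 ms width); non-target stimuli evoke a smaller,
#' earlier response so that target discrimination is nontrivial.  Background
#' sources are AR(2) rhythms resonating in the alpha band (9 and 11 Hz) with a
#' small random-walk drift admixture, scaled to 40 uV RMS (about 300 uV
#' peak-to-peak over a minute of data).  The optional artifact source is a slow piecewise-linear
#' ramp (breakpoints every ~2 s).  With `orthogonalize = TRUE` (default) the
#' non-ERP rows are Gram-Schmidt-decorrelated against the earlier rows over
#' the generated window, realizing the mixing model's premise of mutually
#' uncorrelated sources; the ERP waveform itself is never altered.
#'
#' @param p300Uv P300 peak amplitude in microvolts.
#' @param p300LatencySec,p300SdSec peak latency and Gaussian width in seconds.
#' @param nontargetScale amplitude of the non-target response relative to the
#'   target's.
#' @param nontargetLatencySec,nontargetSdSec latency and width of the
#'   non-target response.
#' @param backgroundUv background RMS amplitude in microvolts.
#' @param nBackground number of background sources.
#' @param bgFreqsHz,bgPoleRadius AR(2) resonance frequencies (Hz) and pole
#'   radii, recycled over the background sources.
#' @param driftFraction fraction of background variance contributed by
#'   random-walk drift.
#' @param artifact logical, include the artifact source.
#' @param artifactUv artifact RMS amplitude in microvolts.
#' @param rampSec mean spacing of artifact ramp breakpoints in seconds.
#' @param orthogonalize logical, decorrelate rows exactly over the window.
#'
#' @return A named list of parameters for [generateSources()].
#' @export
sourceParams <- function(p300Uv = 1.5, p300LatencySec = 0.300,
                         p300SdSec = 0.060, nontargetScale = 0.3,
                         nontargetLatencySec = 0.180, nontargetSdSec = 0.040,
                         backgroundUv = 40, nBackground = 2L,
                         bgFreqsHz = c(9, 11), bgPoleRadius = c(0.95, 0.90),
                         driftFraction = 0.05, artifact = TRUE,
                         artifactUv = 80, rampSec = 2,
                         orthogonalize = TRUE) {
  as.list(environment())
}

#' Generate ground-truth sources for a stimulus schedule
#'
#' Produces the source matrix underlying a synthetic oddball session: one
#' event-related (P300-like) source locked to the schedule, `nBackground`
#' colored background sources, and optionally one slow artifact source.  Rows
#' are zero-mean and, by construction, mutually uncorrelated over the window.
#'
#' @param events an [EventSequence-class].
#' @param duration recording length in seconds; must cover the last onset plus
#'   0.7 s.
#' @param fs sampling rate in Hz.
#' @param params parameter list from [sourceParams()].
#' @param seed integer seed for all stochastic waveforms.
#'
#' @return A [SourceSet-class] whose first row is the ERP source.
#' @examples
#' ev <- generateStimulusSequence(2, seed = 1)
#' src <- generateSources(ev, duration = 10, seed = 1)
#' src
#' @export
generateSources <- function(events, duration, fs = 256,
                            params = sourceParams(), seed = 1L) {
  n <- round(duration * fs)
  if (length(events) > 0 &&
      duration < max(onsets(events)) + 0.7 - 1e-9)
    stop("duration too short: must cover the last onset + 0.7 s", call. = FALSE)
  p <- utils::modifyList(sourceParams(), params)
  withSeed(seed, {
    tt <- (seq_len(n) - 1) / fs
    bump <- function(latency, sdSec, amp, at) {
      out <- numeric(n)
      for (o in at) out <- out + amp * exp(-((tt - o - latency)^2) / (2 * sdSec^2))
      out
    }
    erp <- numeric(n)
    if (length(events) > 0 && p$p300Uv != 0) {
      tgt <- onsets(events)[isTarget(events)]
      non <- onsets(events)[!isTarget(events)]
      erp <- bump(p$p300LatencySec, p$p300SdSec, p$p300Uv, tgt) +
        bump(p$nontargetLatencySec, p$nontargetSdSec,
             p$nontargetScale * p$p300Uv, non)
    }
    rows <- list(erp)
    kinds <- "erp"
    ar2 <- function(f0, r) {
      w <- 2 * pi * f0 / fs
      as.numeric(stats::filter(rnorm(n), c(2 * r * cos(w), -r^2),
                               method = "recursive"))
    }
    for (j in seq_len(p$nBackground)) {
      f0 <- p$bgFreqsHz[(j - 1) %% length(p$bgFreqsHz) + 1]
      r <- p$bgPoleRadius[(j - 1) %% length(p$bgPoleRadius) + 1]
      x <- ar2(f0, r)
      if (p$driftFraction > 0) {
        d <- cumsum(rnorm(n)); d <- d - mean(d)
        x <- x / sd(x) * sqrt(1 - p$driftFraction) +
          d / sd(d) * sqrt(p$driftFraction)
      }
      rows <- c(rows, list(x)); kinds <- c(kinds, "background")
    }
    if (isTRUE(p$artifact)) {
      nb <- ceiling(duration / p$rampSec) + 1
      bp <- sort(unique(c(1, n, sample(2:(n - 1), min(nb, n - 2)))))
      art <- approx(bp, rnorm(length(bp)), xout = seq_len(n))$y
      rows <- c(rows, list(art)); kinds <- c(kinds, "artifact")
    }
    S <- do.call(rbind, rows)
    S <- S - rowMeans(S)
    if (isTRUE(p$orthogonalize) && nrow(S) > 1) {
      # Gram-Schmidt: later rows are decorrelated against earlier ones; the
      # ERP row (first) is left untouched.
      for (i in 2:nrow(S)) for (j in 1:(i - 1)) {
        denom <- sum(S[j, ]^2)
        if (denom > 0)
          S[i, ] <- S[i, ] - sum(S[i, ] * S[j, ]) / denom * S[j, ]
      }
      S <- S - rowMeans(S)
    }
    targetRms <- c(erp = NA_real_, background = p$backgroundUv,
                   artifact = p$artifactUv)
    for (i in seq_len(nrow(S))) {
      if (kinds[i] == "erp") next  # ERP keeps its physical amplitude
      r <- sqrt(mean(S[i, ]^2))
      if (r > 0) S[i, ] <- S[i, ] / r * targetRms[kinds[i]]
    }
    rownames(S) <- NULL
    new("SourceSet", S = S, kinds = kinds, fs = fs)
  })
}

#' Draw a well-conditioned random mixing matrix
#'
#' Draws an M x N matrix with standard-normal entries and unit-norm columns,
#' redrawing until the condition number is below `condBound` (an SVD clip is
#' applied as a last resort).
#'
#' @param M number of channels (rows), `M >= N`.
#' @param N number of sources (columns).
#' @param seed integer seed.
#' @param condBound upper bound on the condition number.
#' @param noiseSigma sensor-noise standard deviation (microvolts) carried by
#'   the model for [mixSources()].
#'
#' @return A [MixtureModel-class].
#' @export
makeMixing <- function(M = 8L, N = 4L, seed = 1L, condBound = 10,
                       noiseSigma = 0) {
  stopDim(M >= N && N >= 1, "dimension error: M >= N >= 1 is required")
  withSeed(seed, {
    A <- NULL
    for (i in 1:200) {
      cand <- matrix(rnorm(M * N), M, N)
      cand <- sweep(cand, 2, sqrt(colSums(cand^2)), "/")
      if (N == 1 || kappa(cand, exact = TRUE) <= condBound) { A <- cand; break }
    }
    if (is.null(A)) {  # SVD clip: compress the singular spread, renormalize
      sv <- svd(cand)
      dclip <- pmax(sv$d, max(sv$d) / condBound)
      A <- sv$u %*% diag(dclip, N) %*% t(sv$v)
      A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    }
    new("MixtureModel", A = A, noiseSigma = noiseSigma,
        seed = as.integer(seed))
  })
}

#' Mix sources into a sensor recording
#'
#' Applies the linear instantaneous model `X = A S + noise`, with i.i.d.
#' Gaussian sensor noise of standard deviation `noiseSigma(model)` added per
#' channel and sample.
#'
#' @param sources a [SourceSet-class].
#' @param model a [MixtureModel-class] whose column count equals the source
#'   count.
#' @param seed integer seed for the sensor noise.
#' @param channelLabels labels for the output channels; defaults to the
#'   standard eight-electrode montage when M = 8.
#'
#' @return A [Recording-class].
#' @export
mixSources <- function(sources, model, seed = 1L, channelLabels = NULL) {
  A <- mixingMatrix(model)
  stopDim(ncol(A) == nrow(sources(sources)),
          "dimension mismatch: ncol(A) must equal the source count")
  X <- A %*% sources(sources)
  if (noiseSigma(model) > 0)
    X <- X + withSeed(seed,
      matrix(rnorm(length(X), sd = noiseSigma(model)), nrow(X), ncol(X)))
  new("Recording", X = unname(X), fs = samplingRate(sources),
      channelLabels = channelLabels %||% defaultChannelLabels(nrow(X)))
}

#' Simulate a complete synthetic oddball session
#'
#' Convenience wrapper chaining [generateStimulusSequence()],
#' [generateSources()], [makeMixing()] and [mixSources()] with a single seed.
#'
#' @param nBlocks number of stimulus blocks.
#' @param isi inter-stimulus interval in seconds.
#' @param duration recording length in seconds; defaults to the schedule
#'   length plus one second of lead-in/out.
#' @param fs sampling rate in Hz.
#' @param M number of channels.
#' @param params source parameters, see [sourceParams()].
#' @param noiseSigma sensor-noise standard deviation in microvolts.
#' @param condBound mixing condition-number bound.
#' @param seed integer master seed.
#'
#' @return A list with elements `events`, `sources`, `model` and `recording`.
#' @examples
#' sess <- simulateSession(nBlocks = 4, seed = 1)
#' sess$recording
#' @export
simulateSession <- function(nBlocks = 10L, isi = 0.350, duration = NULL,
                            fs = 256, M = 8L, params = sourceParams(),
                            noiseSigma = 0, condBound = 10, seed = 1L) {
  events <- generateStimulusSequence(nBlocks, isi = isi, seed = seed,
                                     firstOnset = 0.5)
  duration <- duration %||%
    (if (length(events)) max(onsets(events)) + 1 else 10)
  srcs <- generateSources(events, duration = duration, fs = fs,
                          params = params, seed = seed + 1L)
  model <- makeMixing(M = M, N = nrow(sources(srcs)), seed = seed + 2L,
                      condBound = condBound, noiseSigma = noiseSigma)
  rec <- mixSources(srcs, model, seed = seed + 3L)
  list(events = events, sources = srcs, model = model, recording = rec)
}
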