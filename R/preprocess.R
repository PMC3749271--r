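#' Band-pass filter specification constructor
#'
#' @param order overall band-pass order; even, default 6 (a third-order
#'   Butterworth prototype applied as a band-pass).
#' @param lowHz,highHz corner frequencies in Hz (defaults 1 and 12).
#' @param design filter family; `"butterworth"`.
#' @return A [FilterSpec-class].
#' @export
filterSpec <- function(order = 6L, lowHz = 1, highHz = 12,
                       design = "butterworth") {
  new("FilterSpec", order = as.integer(order), lowHz = lowHz,
      highHz = highHz, design = design)
}

#' Band-pass filter a recording
#'
#' Applies the sixth-order 1-12 Hz Butterworth band-pass (or any
#' [filterSpec()]) to every channel.  By default the filter is run
#' forward-backward (zero phase), so the 300 ms P300 peak latency is not
#' distorted; `zeroPhase = FALSE` gives the causal single-pass variant for
#' strict real-time emulation.
#'
#' @param rec a [Recording-class].
#' @param spec a [FilterSpec-class].
#' @param zeroPhase logical; forward-backward (default) or causal.
#' @return The filtered [Recording-class] (same shape).
#' @examples
#' sess <- simulateSession(nBlocks = 2, seed = 1)
#' filt <- bandpassFilter(sess$recording)
#' @export
bandpassFilter <- function(rec, spec = filterSpec(), zeroPhase = TRUE) {
  fs <- samplingRate(rec)
  if (spec@highHz >= fs / 2)
    stop("configuration error: highHz must be below the Nyquist frequency",
         call. = FALSE)
  validObject(spec)
  bf <- signal::butter(spec@order / 2,
                       c(spec@lowHz, spec@highHz) / (fs / 2), type = "pass")
  X <- recData(rec)
  Y <- t(apply(X, 1, function(ch) {
    if (zeroPhase) signal::filtfilt(bf, ch) else signal::filter(bf, ch)
  }))
  new("Recording", X = unname(as.matrix(Y)), fs = fs,
      channelLabels = channelLabels(rec))
}

#' Theoretical band-pass magnitude response
#'
#' Magnitude of the designed filter at the requested frequencies, as applied:
#' with `zeroPhase = TRUE` the forward-backward pass squares the single-pass
#' magnitude.  Exposed so that empirical attenuation can be validated against
#' the design.
#'
#' @param spec a [FilterSpec-class].
#' @param freqHz frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param zeroPhase as in [bandpassFilter()].
#' @return Numeric vector of linear gains.
#' @export
filterResponse <- function(spec, freqHz, fs = 256, zeroPhase = TRUE) {
  bf <- signal::butter(spec@order / 2,
                       c(spec@lowHz, spec@highHz) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freqHz / fs)
  evalPoly <- function(coef, z) {
    out <- 0 + 0i
    for (cf in coef) out <- out * z + cf
    out
  }
  g <- Mod(evalPoly(bf$b, z) / evalPoly(bf$a, z))
  if (zeroPhase) g^2 else g
}

#' Extract stimulus-locked epochs
#'
#' Cuts one window per event from a recording and baseline-corrects it.  The
#' onset sample is `round(onset * fs)` (0-based) and the window is closed at
#' both ends, so a \[0, 0.7\] s window at 256 Hz yields 180 samples.
#'
#' @param rec a [Recording-class].
#' @param events an [EventSequence-class]; every window must fall inside the
#'   recording.
#' @param window numeric(2), window limits in seconds relative to onset.
#' @param baseline numeric(2), interval whose per-channel mean is subtracted;
#'   defaults to the first 100 ms of the window.
#' @return An [EpochSet-class].
#' @export
extractEpochs <- function(rec, events, window = c(-0.1, 0.7),
                          baseline = c(window[1], window[1] + 0.1)) {
  fs <- samplingRate(rec)
  X <- recData(rec)
  i0 <- round(window[1] * fs)
  i1 <- round(window[2] * fs)
  nw <- i1 - i0 + 1L
  on <- round(onsets(events) * fs)  # 0-based onset samples
  lo <- on + i0
  hi <- on + i1
  bad <- which(lo < 0 | hi >= ncol(X))
  if (length(bad))
    stop("input error: window exceeds recording bounds for events ",
         paste(bad, collapse = ", "), call. = FALSE)
  b0 <- round(baseline[1] * fs) - i0 + 1L
  b1 <- round(baseline[2] * fs) - i0 + 1L
  if (b0 < 1 || b1 > nw || b1 < b0)
    stop("baseline interval must lie inside the window", call. = FALSE)
  out <- array(0, dim = c(length(on), nrow(X), nw))
  for (e in seq_along(on)) {
    sl <- X[, (lo[e] + 1L):(hi[e] + 1L), drop = FALSE]  # to 1-based
    sl <- sl - rowMeans(sl[, b0:b1, drop = FALSE])
    out[e, , ] <- sl
  }
  new("EpochSet", data = out, window = window, baseline = baseline,
      fs = fs, events = events)
}

#' Time axis of an epoch window
#'
#' @param x an [EpochSet-class].
#' @return Numeric vector of sample times in seconds relative to onset.
#' @export
epochTimes <- function(x) {
  fs <- samplingRate(x)
  (round(x@window[1] * fs):round(x@window[2] * fs)) / fs
}
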