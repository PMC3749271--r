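#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "SourceSet", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
setMethod("recData", "Recording", function(x) x@X)
#' @rdname accessors
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("nChannels", "Recording", function(x) nrow(x@X))
#' @rdname accessors
setMethod("nSamples", "Recording", function(x) ncol(x@X))

#' @describeIn accessors channels x samples dimensions of a recording.
#' @export
setMethod("dim", "Recording", function(x) dim(x@X))

#' @rdname accessors
setMethod("sources", "SourceSet", function(x) x@S)
#' @rdname accessors
setMethod("sourceKinds", "SourceSet", function(x) x@kinds)

#' @rdname accessors
setMethod("mixingMatrix", "MixtureModel", function(x) x@A)
#' @rdname accessors
setMethod("noiseSigma", "MixtureModel", function(x) x@noiseSigma)

#' @rdname accessors
setMethod("onsets", "EventSequence", function(x) x@onsets)
#' @rdname accessors
setMethod("stimulusIds", "EventSequence", function(x) x@stimulus)
#' @rdname accessors
setMethod("blockIds", "EventSequence", function(x) x@block)
#' @rdname accessors
setMethod("targetId", "EventSequence", function(x) x@targetId)
#' @rdname accessors
setMethod("isTarget", "EventSequence", function(x) x@stimulus == x@targetId)

#' @describeIn accessors number of events in a schedule.
#' @export
setMethod("length", "EventSequence", function(x) length(x@onsets))

#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname accessors
setMethod("piValue", "QualityReport", function(x) x@PI)
#' @rdname accessors
setMethod("piDecibel", "QualityReport", function(x) x@PIdb)
#' @rdname accessors
setMethod("piTrajectory", "QualityReport", function(x) x@piTrajectory)
#' @rdname accessors
setMethod("convergedEpoch", "QualityReport", function(x) x@convergedEpoch)

#' @rdname accessors
setMethod("predictions", "ClassificationResult", function(x) x@predicted)
#' @rdname accessors
setMethod("accuracy", "ClassificationResult", function(x) x@accuracy)

setMethod("show", "EventSequence", function(object) {
  cat(sprintf("EventSequence: %d events, %d blocks, target stimulus %d\n",
              length(object@onsets), length(unique(object@block)),
              object@targetId))
  cat(sprintf("  ISI %.3f s (flash %.3f s + 0.300 s blank)\n",
              object@isi, object@flashDuration))
})

setMethod("show", "SourceSet", function(object) {
  cat(sprintf("SourceSet: %d sources x %d samples at %g Hz\n",
              nrow(object@S), ncol(object@S), object@fs))
  rms <- sqrt(rowMeans(object@S^2))
  for (i in seq_len(nrow(object@S)))
    cat(sprintf("  [%d] %-10s RMS %8.3f uV\n", i, object@kinds[i], rms[i]))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: %d x %d mixing (cond %.2f), noise sd %g uV\n",
              nrow(object@A), ncol(object@A), kappa(object@A, exact = TRUE),
              object@noiseSigma))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@X), ncol(object@X), object@fs,
              ncol(object@X) / object@fs))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples, window [%g, %g] s\n",
              d[1], d[2], d[3], object@window[1], object@window[2]))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: PI = %.4g (%.1f dB)\n", object@PI, object@PIdb))
  if (length(object@epochPi))
    cat(sprintf("  epochs run: %d; converged at epoch %s\n",
                length(object@epochPi),
                ifelse(is.na(object@convergedEpoch), "never",
                       as.character(object@convergedEpoch))))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: accuracy %.3f over %d blocks (m = %d, window [%g, %g] s)\n",
              object@accuracy, length(object@predicted), object@m,
              object@scoreWindow[1], object@scoreWindow[2]))
})

setMethod("show", "BaselineResult", function(object) {
  it <- object@iterationsToThreshold
  cat(sprintf("BaselineResult [%s]: final PI %.4g; iterations to PI<0.1: %s\n",
              object@algorithm, utils::tail(object@piCurve$pi, 1),
              ifelse(is.na(it["0.1"]), "not reached", format(it["0.1"]))))
})

setMethod("show", "MnnModel", function(object) {
  cat(sprintf("MnnModel: layers (%s), activation %s, lr %g, momentum %g\n",
              paste(object@sizes, collapse = ", "), object@activation,
              object@learningRate, object@momentum))
})
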