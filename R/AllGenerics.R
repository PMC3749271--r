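#' Accessor generics
#'
#' Accessors for the core data classes: sampling rates, signal matrices,
#' schedule fields and report fields are read through these generics rather
#' than by slot access.
#'
#' @param x an object of one of the package's classes.
#' @return The requested component; see the methods listed for each class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' @rdname accessors
#' @export
setGeneric("sourceKinds", function(x) standardGeneric("sourceKinds"))

#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname accessors
#' @export
setGeneric("stimulusIds", function(x) standardGeneric("stimulusIds"))

#' @rdname accessors
#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @rdname accessors
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @rdname accessors
#' @export
setGeneric("isTarget", function(x) standardGeneric("isTarget"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("piValue", function(x) standardGeneric("piValue"))

#' @rdname accessors
#' @export
setGeneric("piDecibel", function(x) standardGeneric("piDecibel"))

#' @rdname accessors
#' @export
setGeneric("piTrajectory", function(x) standardGeneric("piTrajectory"))

#' @rdname accessors
#' @export
setGeneric("convergedEpoch", function(x) standardGeneric("convergedEpoch"))

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
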