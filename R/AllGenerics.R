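#' @rdname FrameStack-class
#' @param x,object a `FrameStack`, `HeatMap`, `ClusterProfile`,
#'   `PresenceCalls` or `InteractionMap` object, as documented per method.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname HeatMap-class
#' @export
setGeneric("heat", function(x) standardGeneric("heat"))

#' @rdname HeatMap-class
#' @export
setGeneric("heatLag", function(x) standardGeneric("heatLag"))

#' @rdname HeatMap-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname ClusterProfile-class
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))

#' @rdname ClusterProfile-class
#' @export
setGeneric("profileDetection", function(x) standardGeneric("profileDetection"))

#' @rdname ClusterProfile-class
#' @export
setGeneric("profileCells", function(x) standardGeneric("profileCells"))

#' @rdname PresenceCalls-class
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname PresenceCalls-class
#' @export
setGeneric("presencePolicy", function(x) standardGeneric("presencePolicy"))

#' @rdname InteractionMap-class
#' @export
setGeneric("interactionCounts", function(x) standardGeneric("interactionCounts"))

#' @rdname InteractionMap-class
#' @export
setGeneric("contributingPairs", function(x) standardGeneric("contributingPairs"))

#' @rdname InteractionMap-class
#' @export
setGeneric("skippedPairs", function(x) standardGeneric("skippedPairs"))

# ---- accessors ----

#' @rdname FrameStack-class
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[1L])

#' @rdname FrameStack-class
#' @export
setMethod("sourceId", "FrameStack", function(x) x@sourceId)

#' @rdname HeatMap-class
#' @export
setMethod("heat", "HeatMap", function(x) x@heat)

#' @rdname HeatMap-class
#' @export
setMethod("heatLag", "HeatMap", function(x) x@lag)

#' @rdname HeatMap-class
#' @export
setMethod("nPairs", "HeatMap", function(x) x@nPairs)

#' @rdname HeatMap-class
#' @export
setMethod("sourceId", "HeatMap", function(x) x@sourceId)

#' @rdname ClusterProfile-class
#' @export
setMethod("profileMeans", "ClusterProfile", function(x) x@means)

#' @rdname ClusterProfile-class
#' @export
setMethod("profileDetection", "ClusterProfile", function(x) x@detection)

#' @rdname ClusterProfile-class
#' @export
setMethod("profileCells", "ClusterProfile", function(x) x@nCells)

#' @rdname PresenceCalls-class
#' @export
setMethod("presence", "PresenceCalls", function(x) x@calls)

#' @rdname PresenceCalls-class
#' @export
setMethod("presencePolicy", "PresenceCalls", function(x) {
  c(minDetection = x@minDetection, minMean = x@minMean)
})

#' @rdname InteractionMap-class
#' @export
setMethod("interactionCounts", "InteractionMap", function(x) x@counts)

#' @rdname InteractionMap-class
#' @export
setMethod("contributingPairs", "InteractionMap", function(x) x@contributing)

#' @rdname InteractionMap-class
#' @export
setMethod("skippedPairs", "InteractionMap", function(x) x@skipped)

# ---- show methods ----

#' @rdname FrameStack-class
#' @export
setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameStack '%s': %d frames of %d x %d px, intensities [%.3f, %.3f]\n",
    object@sourceId, d[1L], d[2L], d[3L],
    min(object@frames), max(object@frames)
  ))
  invisible(NULL)
})

#' @rdname HeatMap-class
#' @export
setMethod("show", "HeatMap", function(object) {
  cat(sprintf(
    "HeatMap '%s': %d x %d px, lag %d (%s, %d pairs), max heat %.4g\n",
    object@sourceId, nrow(object@heat), ncol(object@heat),
    object@lag, object@method, object@nPairs, max(object@heat)
  ))
  invisible(NULL)
})

#' @rdname ClusterProfile-class
#' @export
setMethod("show", "ClusterProfile", function(object) {
  cat(sprintf(
    "ClusterProfile: %d genes x %d clusters (%s cells)\n",
    nrow(object@means), ncol(object@means),
    paste(object@nCells, collapse = "/")
  ))
  invisible(NULL)
})

#' @rdname PresenceCalls-class
#' @export
setMethod("show", "PresenceCalls", function(object) {
  cat(sprintf(
    "PresenceCalls: %d genes x %d clusters, %d present (detection >= %.3g & mean >= %.3g)\n",
    nrow(object@calls), ncol(object@calls), sum(object@calls),
    object@minDetection, object@minMean
  ))
  invisible(NULL)
})

#' @rdname InteractionMap-class
#' @export
setMethod("show", "InteractionMap", function(object) {
  cat(sprintf(
    "InteractionMap: %d sender x %d receiver clusters, %d interactions total, %d pairs skipped\n",
    nrow(object@counts), ncol(object@counts), sum(object@counts),
    nrow(object@skipped)
  ))
  invisible(NULL)
})
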