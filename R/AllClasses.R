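#' @import methods
NULL

#' FrameStack: an ordered stack of grayscale video frames
#'
#' Container for one decoded time-lapse video: a `T x H x W` array of
#' intensities on `[0, 1]`, with optional acquisition metadata. All motion
#' quantification in this package operates on a `FrameStack`.
#'
#' @slot frames numeric array, `T x H x W`, values in `[0, 1]`.
#' @slot frameInterval seconds between frames (`NA_real_` when unknown).
#' @slot sourceId free-text identifier of the originating video.
#'
#' @seealso [computeHeatMap()], [simulateContractionVideo()]
#' @export
setClass("FrameStack",
  slots = c(
    frames = "array",
    frameInterval = "numeric",
    sourceId = "character"
  ),
  prototype = prototype(frameInterval = NA_real_, sourceId = "unknown")
)

setValidity("FrameStack", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) {
    return("'frames' must be a 3-dimensional (frame x height x width) array")
  }
  if (anyNA(f) || !all(is.finite(f))) {
    return("'frames' must be finite and free of NA")
  }
  if (min(f) < 0 || max(f) > 1) {
    return("frame intensities must lie in [0, 1]")
  }
  if (length(object@sourceId) != 1L) {
    return("'sourceId' must be a single string")
  }
  TRUE
})

#' HeatMap: per-pixel change heat of one video
#'
#' The per-pixel mean absolute intensity difference at a fixed frame lag
#' ("change heat"). Bright pixels mark regions of strong local motion.
#'
#' @slot heat numeric `H x W` matrix, nonnegative, bounded by 1 for inputs
#'   on `[0, 1]`.
#' @slot lag frame lag the differences were taken at.
#' @slot nPairs number of differenced frame pairs that were averaged.
#' @slot method `"sliding"` or `"disjoint"` pairing of frames.
#' @slot sourceId identifier inherited from the input stack.
#'
#' @seealso [computeHeatMap()], [contractionScore()], [renderHeatImage()]
#' @export
setClass("HeatMap",
  slots = c(
    heat = "matrix",
    lag = "integer",
    nPairs = "integer",
    method = "character",
    sourceId = "character"
  )
)

setValidity("HeatMap", function(object) {
  if (!is.numeric(object@heat)) {
    return("'heat' must be a numeric matrix")
  }
  if (anyNA(object@heat) || min(object@heat) < 0) {
    return("'heat' must be nonnegative and free of NA")
  }
  if (object@lag < 1L) {
    return("'lag' must be a positive integer")
  }
  if (object@nPairs < 1L) {
    return("'nPairs' must be a positive integer")
  }
  TRUE
})

#' ClusterProfile: per-cluster expression summaries
#'
#' For every gene and cluster, the mean normalized expression and the
#' detection fraction (share of cells in which the gene is observed),
#' plus per-cluster cell counts. This is the input to presence calling
#' and to the ligand-receptor screen.
#'
#' @slot means numeric genes x clusters matrix of mean log-normalized
#'   expression.
#' @slot detection numeric genes x clusters matrix of detection fractions
#'   in `[0, 1]`.
#' @slot nCells named integer vector of cells per cluster.
#'
#' @seealso [buildClusterProfile()], [callPresence()], [scorePairings()]
#' @export
setClass("ClusterProfile",
  slots = c(
    means = "matrix",
    detection = "matrix",
    nCells = "integer"
  )
)

setValidity("ClusterProfile", function(object) {
  if (!identical(dim(object@means), dim(object@detection))) {
    return("'means' and 'detection' must have identical dimensions")
  }
  if (ncol(object@means) != length(object@nCells)) {
    return("one 'nCells' entry is required per cluster column")
  }
  if (min(object@detection) < 0 || max(object@detection) > 1) {
    return("detection fractions must lie in [0, 1]")
  }
  if (min(object@means) < 0) {
    return("mean normalized expression must be nonnegative")
  }
  TRUE
})

#' PresenceCalls: boolean expressed/absent calls per gene and cluster
#'
#' Binary presence of each gene in each cluster, together with the policy
#' (detection-fraction and mean-expression thresholds) that produced the
#' calls, so they are reproducible from a [ClusterProfile].
#'
#' @slot calls logical genes x clusters matrix.
#' @slot minDetection detection-fraction threshold used.
#' @slot minMean mean-expression threshold used.
#'
#' @seealso [callPresence()], [countInteractions()]
#' @export
setClass("PresenceCalls",
  slots = c(
    calls = "matrix",
    minDetection = "numeric",
    minMean = "numeric"
  )
)

setValidity("PresenceCalls", function(object) {
  if (!is.logical(object@calls)) {
    return("'calls' must be a logical matrix")
  }
  TRUE
})

#' InteractionMap: ligand-receptor interaction counts per ordered cluster pair
#'
#' For every ordered (sender, receiver) cluster pair, the number of database
#' pairs whose ligand is present in the sender and whose receptor is present
#' in the receiver, with the contributing pairs listed per cell-type pair and
#' a report of database pairs skipped because a gene was absent from the
#' expression matrix.
#'
#' @slot counts integer senders x receivers matrix of interaction counts.
#' @slot contributing named list (one element per ordered pair, key
#'   `"sender->receiver"`) of data frames with the contributing ligand and
#'   receptor genes.
#' @slot skipped data frame of database pairs that referenced genes absent
#'   from the profile.
#'
#' @seealso [countInteractions()], [renderInteractionHeatmap()]
#' @export
setClass("InteractionMap",
  slots = c(
    counts = "matrix",
    contributing = "list",
    skipped = "data.frame"
  )
)

setValidity("InteractionMap", function(object) {
  if (length(object@contributing) != length(object@counts)) {
    return("one contributing-pair list entry is required per cell of 'counts'")
  }
  for (s in rownames(object@counts)) {
    for (r in colnames(object@counts)) {
      key <- paste0(s, "->", r)
      if (!key %in% names(object@contributing)) {
        return(sprintf("missing contributing-pair entry for '%s'", key))
      }
      if (object@counts[s, r] != nrow(object@contributing[[key]])) {
        return(sprintf(
          "count for '%s' (%d) does not match its contributing-pair list (%d)",
          key, object@counts[s, r], nrow(object@contributing[[key]])
        ))
      }
    }
  }
  TRUE
})
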