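#' Summarize expression per cluster
#'
#' Computes, for every gene and cluster, the mean log-normalized expression
#' and the detection fraction (share of the cluster's cells in which the
#' gene is observed), the two summaries the presence calls and the pairing
#' scores are built from.
#'
#' @param x a `SingleCellExperiment` with `logcounts`, or a log-normalized
#'   genes x cells matrix.
#' @param labels factor of cluster labels, one per cell (defaults to
#'   `colLabels(x)` for a `SingleCellExperiment`). Labels must cover exactly
#'   the cells of the matrix.
#'
#' @return A [ClusterProfile-class].
#' @export
buildClusterProfile <- function(x, labels = NULL) {
  nm <- .logcounts(x)
  detector <- nm > 0
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- SingleCellExperiment::colLabels(x)
    if ("counts" %in% SummarizedExperiment::assayNames(x)) {
      detector <- SummarizedExperiment::assay(x, "counts") > 0
    }
  }
  if (is.null(labels)) stop("'labels' are required")
  labels <- factor(labels)
  if (length(labels) != ncol(nm) || anyNA(labels)) {
    stop("labels must reference exactly the cells of the matrix")
  }
  cls <- levels(labels)
  genes <- rownames(nm)
  means <- matrix(0, nrow(nm), length(cls), dimnames = list(genes, cls))
  det <- means
  nCells <- integer(length(cls))
  names(nCells) <- cls
  for (k in seq_along(cls)) {
    i <- labels == cls[k]
    nCells[k] <- sum(i)
    means[, k] <- Matrix::rowMeans(nm[, i, drop = FALSE])
    det[, k] <- Matrix::rowMeans(detector[, i, drop = FALSE])
  }
  new("ClusterProfile", means = means, detection = det, nCells = nCells)
}

#' Call gene presence per cluster
#'
#' A gene is called present in a cluster when it is detected in at least
#' `minDetection` of the cluster's cells AND its mean log-normalized
#' expression reaches `minMean`. The dual rule guards against both
#' sporadic high counts in a few cells and diffuse background expression;
#' the thresholds are recorded in the result so calls are reproducible.
#'
#' @param profile a [ClusterProfile-class].
#' @param minDetection minimum detection fraction (default 0.1).
#' @param minMean minimum mean log-normalized expression (default 0.25).
#'
#' @return A [PresenceCalls-class].
#' @export
callPresence <- function(profile, minDetection = 0.1, minMean = 0.25) {
  stopifnot(methods::is(profile, "ClusterProfile"))
  if (minDetection < 0 || minDetection > 1) {
    stop("'minDetection' must lie in [0, 1]")
  }
  if (minMean < 0) stop("'minMean' must be nonnegative")
  calls <- profile@detection >= minDetection & profile@means >= minMean
  new("PresenceCalls",
    calls = calls, minDetection = minDetection, minMean = minMean
  )
}

#' Count putative ligand-receptor interactions between cluster pairs
#'
#' For every ordered (sender, receiver) pair of clusters, counts the
#' database pairs whose ligand is called present in the sender cluster and
#' whose receptor is called present in the receiver cluster, and records the
#' contributing pairs. Database pairs referencing genes absent from the
#' expression profile are skipped and reported, not treated as errors (pair
#' databases routinely exceed the detected gene set).
#'
#' @param calls a [PresenceCalls-class].
#' @param db ligand-receptor pair data frame with columns `ligand` and
#'   `receptor` (unique rows).
#' @param senders,receivers cluster ids (must be columns of the calls
#'   matrix); default to all clusters for both roles.
#'
#' @return An [InteractionMap-class].
#' @export
countInteractions <- function(calls, db, senders = NULL, receivers = NULL) {
  stopifnot(methods::is(calls, "PresenceCalls"))
  db <- as.data.frame(db)
  if (!all(c("ligand", "receptor") %in% names(db))) {
    stop("'db' needs 'ligand' and 'receptor' columns")
  }
  if (anyDuplicated(db[, c("ligand", "receptor")])) {
    stop("'db' contains duplicate (ligand, receptor) rows")
  }
  cm <- calls@calls
  cls <- colnames(cm)
  if (is.null(senders)) senders <- cls
  if (is.null(receivers)) receivers <- cls
  senders <- as.character(senders)
  receivers <- as.character(receivers)
  if (!all(c(senders, receivers) %in% cls)) {
    stop("senders/receivers must be cluster ids present in the calls")
  }

  known <- db$ligand %in% rownames(cm) & db$receptor %in% rownames(cm)
  skipped <- db[!known, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- "gene absent from expression profile"
  use <- db[known, , drop = FALSE]

  counts <- matrix(0L, length(senders), length(receivers),
                   dimnames = list(senders, receivers))
  contributing <- list()
  for (s in senders) {
    ligOK <- cm[use$ligand, s]
    for (r in receivers) {
      hit <- ligOK & cm[use$receptor, r]
      counts[s, r] <- sum(hit)
      contributing[[paste0(s, "->", r)]] <-
        use[hit, c("ligand", "receptor"), drop = FALSE]
    }
  }
  new("InteractionMap",
    counts = counts, contributing = contributing,
    skipped = as.data.frame(skipped)
  )
}

#' Mean interaction count per sender cluster
#'
#' Secondary summary of an [InteractionMap-class]: the mean interaction
#' count of each sender cluster over the receiver clusters.
#'
#' @param imap an [InteractionMap-class].
#' @return Named numeric vector, one value per sender cluster.
#' @export
senderMeans <- function(imap) {
  stopifnot(methods::is(imap, "InteractionMap"))
  rowMeans(imap@counts)
}

#' Score and rank ligand-receptor pairings between cluster sets
#'
#' Scores every (ligand, receptor, sender, receiver) combination by the
#' product of the ligand's mean expression in the sender cluster and the
#' receptor's mean expression in the receiver cluster -- the simplest score
#' monotone in both sides -- and returns the table ranked by score
#' descending. Ties are broken lexicographically by (ligand, receptor,
#' sender, receiver) so the ranking is deterministic. Pairs referencing
#' genes absent from the profile are skipped.
#'
#' @param profile a [ClusterProfile-class].
#' @param db ligand-receptor pair data frame (`ligand`, `receptor` columns).
#' @param senders,receivers cluster ids; default to all clusters.
#'
#' @return A data frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `ligand_mean`, `receptor_mean`, `score`, ranked by
#'   decreasing score.
#' @seealso [topPairings()]
#' @export
scorePairings <- function(profile, db, senders = NULL, receivers = NULL) {
  stopifnot(methods::is(profile, "ClusterProfile"))
  db <- as.data.frame(db)
  mu <- profile@means
  cls <- colnames(mu)
  if (is.null(senders)) senders <- cls
  if (is.null(receivers)) receivers <- cls
  senders <- as.character(senders)
  receivers <- as.character(receivers)
  if (!all(c(senders, receivers) %in% cls)) {
    stop("senders/receivers must be cluster ids present in the profile")
  }
  use <- db[db$ligand %in% rownames(mu) & db$receptor %in% rownames(mu), ,
            drop = FALSE]

  grid <- expand.grid(
    pair = seq_len(nrow(use)), sender = senders, receiver = receivers,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  out <- data.frame(
    ligand = use$ligand[grid$pair],
    receptor = use$receptor[grid$pair],
    sender = grid$sender,
    receiver = grid$receiver,
    stringsAsFactors = FALSE
  )
  out$ligand_mean <- mu[cbind(out$ligand, out$sender)]
  out$receptor_mean <- mu[cbind(out$receptor, out$receiver)]
  out$score <- out$ligand_mean * out$receptor_mean
  out <- out[order(-out$score, out$ligand, out$receptor,
                   out$sender, out$receiver), ]
  rownames(out) <- NULL
  out
}

#' Head of a ranked pairing table
#'
#' @param pairings ranked table from [scorePairings()].
#' @param k number of top rows to keep (default 50); the full table is
#'   returned when it is shorter than `k`.
#' @return The first `min(k, nrow)` rows.
#' @export
topPairings <- function(pairings, k = 50L) {
  utils::head(pairings, k)
}

#' Write an interaction map as CSV and a PNG heatmap
#'
#' Writes the count matrix to `<pathPrefix>_counts.csv`, a linear-scale
#' heatmap image to `<pathPrefix>.png` (annotated color scale), and a JSON
#' sidecar with the scale bounds; a constant (e.g. all-zero) map is flagged
#' in the sidecar as `degenerate_scale`.
#'
#' @param imap an [InteractionMap-class].
#' @param pathPrefix output path prefix.
#' @return Invisibly, the sidecar metadata list.
#' @export
renderInteractionHeatmap <- function(imap, pathPrefix) {
  stopifnot(methods::is(imap, "InteractionMap"))
  cm <- imap@counts
  csv <- paste0(pathPrefix, "_counts.csv")
  utils::write.csv(as.data.frame(cm), csv, row.names = TRUE)

  pngPath <- paste0(pathPrefix, ".png")
  lo <- min(cm)
  hi <- max(cm)
  grDevices::png(pngPath, width = 640, height = 560)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(
    x = seq_len(ncol(cm)), y = seq_len(nrow(cm)),
    z = t(cm)[, rev(seq_len(nrow(cm))), drop = FALSE],
    col = pal, axes = FALSE,
    zlim = if (lo == hi) c(lo, lo + 1) else c(lo, hi),
    xlab = "receiver cluster", ylab = "sender cluster",
    main = sprintf("Ligand-receptor interactions (min %d, max %d)", lo, hi)
  )
  graphics::axis(1, at = seq_len(ncol(cm)), labels = colnames(cm))
  graphics::axis(2, at = seq_len(nrow(cm)), labels = rev(rownames(cm)), las = 2)
  graphics::box()

  meta <- list(
    scale_min = lo, scale_max = hi,
    degenerate_scale = lo == hi,
    senders = rownames(cm), receivers = colnames(cm),
    skipped_pairs = nrow(imap@skipped)
  )
  jsonlite::write_json(meta, paste0(pathPrefix, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(meta)
}
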