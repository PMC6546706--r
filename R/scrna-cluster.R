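#' Cluster cells on a PC embedding via a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the PC embedding (Euclidean
#' distance, each cell's neighborhood including itself), weights edges by
#' the Jaccard overlap of the two cells' neighborhoods (shared nearest
#' neighbors), prunes weak edges, and partitions the graph by
#' modularity-based Louvain community detection. Clusters are relabeled by
#' decreasing size with contiguous ids starting at 0, and the run is
#' deterministic under a fixed seed.
#'
#' @param embedding cells x PCs numeric matrix (e.g. `runPCA()$embedding`),
#'   or an `ScPCA` object.
#' @param nPCsUsed number of leading PCs to use; defaults to all columns.
#' @param resolution Louvain resolution parameter (default 0.8; larger
#'   values give more clusters).
#' @param kNeighbors neighborhood size (default 20; reduced with a warning
#'   when there are fewer cells).
#' @param pruneJaccard edges with Jaccard weight below this are dropped
#'   (default 1/15).
#' @param seed integer seed for the community detection.
#'
#' @return A factor of cluster labels (levels `"0"`, `"1"`, ... in
#'   decreasing cluster size), named by cell id.
#' @export
clusterCells <- function(embedding, nPCsUsed = NULL, resolution = 0.8,
                         kNeighbors = 20L, pruneJaccard = 1 / 15,
                         seed = 1L) {
  if (inherits(embedding, "ScPCA")) embedding <- embedding$embedding
  embedding <- as.matrix(embedding)
  if (!is.null(nPCsUsed)) {
    nPCsUsed <- min(as.integer(nPCsUsed), ncol(embedding))
    embedding <- embedding[, seq_len(nPCsUsed), drop = FALSE]
  }
  n <- nrow(embedding)
  if (n < 2L) stop("at least two cells are required for clustering")
  kNeighbors <- as.integer(kNeighbors)
  if (kNeighbors >= n) {
    warning("'kNeighbors' reduced to ", n - 1L, " (fewer cells than neighbors)")
    kNeighbors <- n - 1L
  }

  d <- as.matrix(stats::dist(embedding))
  # neighborhood membership matrix; each cell's neighborhood includes itself
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbrs <- setdiff(order(d[i, ]), i)[seq_len(kNeighbors)]
    A[i, c(i, nbrs)] <- 1
  }
  inter <- Matrix::tcrossprod(A)
  jac <- inter / (2 * (kNeighbors + 1L) - inter)
  jac[lower.tri(jac, diag = TRUE)] <- 0
  keep <- which(jac >= pruneJaccard, arr.ind = TRUE)
  if (!nrow(keep)) stop("the SNN graph has no edges; increase 'kNeighbors'")
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- jac[keep]

  comm <- withSeed(seed, {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  lab <- factor(relabel[as.character(memb)], levels = 0:(length(sizes) - 1L))
  names(lab) <- rownames(embedding)
  lab
}

#' One-vs-rest cluster marker detection
#'
#' For every cluster, genes whose mean log-normalized expression differs
#' from the rest of the cells by at least `logfcThreshold` (natural-log
#' units, either direction) are tested with the Wilcoxon rank-sum test, and
#' p-values are Benjamini-Hochberg adjusted across the whole marker table.
#' Detection fractions inside and outside the cluster are reported alongside.
#'
#' @param x a `SingleCellExperiment` with `logcounts` (and, when available,
#'   `counts` for detection fractions), or a log-normalized matrix.
#' @param labels factor of cluster labels, one per cell (defaults to
#'   `colLabels(x)` for a `SingleCellExperiment`).
#' @param logfcThreshold minimum absolute difference of mean log expression
#'   (default 0.25).
#'
#' @return A data frame sorted by cluster then adjusted p-value with columns
#'   `gene`, `cluster`, `logFC`, `pValue`, `pAdj`, `pctIn`, `pctOut`. Every
#'   row satisfies `abs(logFC) >= logfcThreshold`.
#' @export
findMarkers <- function(x, labels = NULL, logfcThreshold = 0.25) {
  nm <- as.matrix(.logcounts(x))
  detector <- nm > 0
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- SingleCellExperiment::colLabels(x)
    if ("counts" %in% SummarizedExperiment::assayNames(x)) {
      detector <- as.matrix(SummarizedExperiment::assay(x, "counts")) > 0
    }
  }
  if (is.null(labels)) stop("'labels' are required")
  labels <- factor(labels)
  if (length(labels) != ncol(nm)) {
    stop("one label per cell is required")
  }
  if (nlevels(labels) < 2L) stop("marker detection needs at least two clusters")

  genes <- rownames(nm)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(nm)))
  rows <- list()
  for (cl in levels(labels)) {
    inCl <- labels == cl
    if (sum(inCl) < 2L) {
      warning("cluster '", cl, "' has fewer than 2 cells; skipped")
      next
    }
    meanIn <- rowMeans(nm[, inCl, drop = FALSE])
    meanOut <- rowMeans(nm[, !inCl, drop = FALSE])
    lfc <- meanIn - meanOut
    cand <- which(abs(lfc) >= logfcThreshold)
    if (!length(cand)) next
    p <- vapply(cand, function(g) {
      suppressWarnings(stats::wilcox.test(
        nm[g, inCl], nm[g, !inCl], exact = FALSE
      )$p.value)
    }, numeric(1))
    rows[[cl]] <- data.frame(
      gene = genes[cand], cluster = cl, logFC = lfc[cand], pValue = p,
      pctIn = rowMeans(detector[cand, inCl, drop = FALSE]),
      pctOut = rowMeans(detector[cand, !inCl, drop = FALSE]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (!length(rows)) {
    return(data.frame(
      gene = character(), cluster = character(), logFC = numeric(),
      pValue = numeric(), pAdj = numeric(), pctIn = numeric(),
      pctOut = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$pValue, method = "BH")
  out <- out[order(out$cluster, out$pAdj, out$gene), ]
  rownames(out) <- NULL
  out[, c("gene", "cluster", "logFC", "pValue", "pAdj", "pctIn", "pctOut")]
}
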