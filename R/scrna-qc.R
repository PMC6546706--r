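# Pull a counts matrix out of an SCE or pass a matrix through.
.counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

.logcounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x)) {
      stop("no 'logcounts' assay; run logNormalize() first")
    }
    SummarizedExperiment::assay(x, "logcounts")
  } else {
    x
  }
}

#' Filter lowly expressed genes
#'
#' Keeps exactly the genes observed above a count threshold in at least
#' `minCells` cells; with the defaults, a gene survives when its count
#' exceeds 1 in three or more cells. The comparison is strict (`count >
#' minCount`), the cell set is untouched and gene order is preserved, so the
#' filter is idempotent.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay, or a genes x
#'   cells count matrix.
#' @param minCount counts must exceed this value (strictly) to qualify.
#' @param minCells minimum number of qualifying cells.
#'
#' @return The input with non-qualifying genes removed. An empty result is
#'   allowed but warned about.
#' @export
filterGenes <- function(x, minCount = 1, minCells = 3L) {
  m <- .counts(x)
  keep <- Matrix::rowSums(m > minCount) >= minCells
  if (!any(keep)) {
    warning("no gene passed the expression filter")
  }
  x[keep, , drop = FALSE]
}

#' Filter cells with too few detected genes
#'
#' Removes cells in which fewer than `minGenes` genes are detected (count
#' greater than zero), the standard low-complexity/failed-library QC rule.
#' Intended to run after [filterGenes()].
#'
#' @param x a `SingleCellExperiment` or count matrix.
#' @param minGenes minimum number of detected genes per cell (default 1000,
#'   appropriate for full-transcript single-cell libraries; scale it down
#'   for small simulated panels).
#'
#' @return The input with failing cells removed.
#' @export
filterCells <- function(x, minGenes = 1000L) {
  m <- .counts(x)
  keep <- Matrix::colSums(m > 0) >= minGenes
  if (!any(keep)) {
    stop(
      "all cells were removed by the >= ", minGenes,
      " detected-genes rule; review the threshold against the data's scale"
    )
  }
  x[, keep, drop = FALSE]
}

#' Log-normalize counts to a fixed per-cell total
#'
#' Normalizes each cell's counts by its total, multiplies by `scaleFactor`
#' and applies the natural log of one plus the result:
#' `value = ln(1 + count * scaleFactor / total)`. Cell totals are computed on
#' the matrix as given (i.e. after any gene filtering), which makes the
#' identity `sum(exp(value) - 1) == scaleFactor` exact per cell.
#'
#' @param x a `SingleCellExperiment` (counts assay) or count matrix; every
#'   cell must have a positive total.
#' @param scaleFactor target per-cell total (default 10000).
#'
#' @return For a `SingleCellExperiment`, the object with a `logcounts`
#'   assay added; for a matrix, the normalized matrix.
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  m <- .counts(x)
  totals <- Matrix::colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[which(totals <= 0)[1L]]
    if (is.null(bad)) bad <- which(totals <= 0)[1L]
    stop("cell '", bad, "' has zero total counts and cannot be normalized")
  }
  if (methods::is(m, "sparseMatrix")) {
    nm <- methods::as(m, "CsparseMatrix")
    nm@x <- log1p(nm@x * scaleFactor / rep.int(totals, diff(nm@p)))
  } else {
    nm <- log1p(sweep(m * scaleFactor, 2L, totals, `/`))
  }
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "logcounts") <- nm
    x
  } else {
    nm
  }
}
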