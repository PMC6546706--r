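#' Write an expression matrix to disk
#'
#' Writes either the sparse MatrixMarket triplet layout (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv`, plus `labels.tsv` when cluster labels are
#' present) or a dense CSV with genes as rows. Counts round-trip exactly
#' through either format.
#'
#' @param x a `SingleCellExperiment` or a genes x cells matrix.
#' @param dir output directory for `format = "mtx"`; the CSV file path for
#'   `format = "csv"`.
#' @param format `"mtx"` or `"csv"`.
#' @param assay assay to write for a `SingleCellExperiment` (default
#'   `"counts"`; use `"logcounts"` for the normalized matrix).
#'
#' @return Invisibly, the paths written.
#' @export
writeExpression <- function(x, dir, format = c("mtx", "csv"),
                            assay = "counts") {
  format <- match.arg(format)
  labels <- NULL
  if (methods::is(x, "SummarizedExperiment")) {
    labels <- SingleCellExperiment::colLabels(x)
    m <- SummarizedExperiment::assay(x, assay)
  } else {
    m <- x
  }
  if (format == "csv") {
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, dir, row.names = FALSE)
    return(invisible(dir))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paths[1L])
  writeLines(rownames(m), paths[2L])
  writeLines(colnames(m), paths[3L])
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(cell = colnames(m), cluster = as.character(labels)),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, file.path(dir, "labels.tsv"))
  }
  invisible(paths)
}

#' Read an expression matrix
#'
#' Reads the MatrixMarket triplet layout (`matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` [+ `labels.tsv`]) or a dense CSV with a leading `gene`
#' column. Dimensions declared by the `.mtx` header are validated against
#' the id files, and in raw mode every entry must be a nonnegative integer.
#'
#' @param path the directory (mtx) or file (csv) to read.
#' @param format `"mtx"` or `"csv"`.
#' @param raw require integer counts (default TRUE; set FALSE when reading
#'   a normalized real-valued matrix).
#'
#' @return A `SingleCellExperiment` with a `counts` assay (raw mode) or a
#'   `logcounts` assay (`raw = FALSE`), and `colLabels` set when a
#'   `labels.tsv` is present.
#' @export
readExpression <- function(path, format = c("mtx", "csv"), raw = TRUE) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1L] != "gene") {
      stop("dense CSV must have a leading 'gene' column")
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    genes <- df$gene
    cells <- colnames(m)
    labels <- NULL
  } else {
    mtx <- file.path(path, "matrix.mtx")
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(m) != length(genes)) {
      stop(sprintf(
        "matrix.mtx declares %d genes but genes.tsv lists %d",
        nrow(m), length(genes)
      ))
    }
    if (ncol(m) != length(cells)) {
      stop(sprintf(
        "matrix.mtx declares %d cells but barcodes.tsv lists %d",
        ncol(m), length(cells)
      ))
    }
    dimnames(m) <- list(genes, cells)
    labels <- NULL
    labPath <- file.path(path, "labels.tsv")
    if (file.exists(labPath)) {
      lab <- utils::read.table(labPath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      if (!all(c("cell", "cluster") %in% names(lab))) {
        stop("labels.tsv needs 'cell' and 'cluster' columns")
      }
      if (!setequal(lab$cell, cells)) {
        stop("labels.tsv cells do not match barcodes.tsv")
      }
      labels <- factor(lab$cluster[match(cells, lab$cell)])
    }
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (anyDuplicated(cells)) stop("duplicate cell ids")
  if (raw) {
    bad <- which(m@x %% 1 != 0 | m@x < 0)
    if (length(bad)) {
      stop(sprintf(
        "non-integer or negative count at entry %d (value %g)",
        bad[1L], m@x[bad[1L]]
      ))
    }
  }
  dimnames(m) <- list(genes, cells)
  assays <- if (raw) list(counts = m) else list(logcounts = m)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = assays)
  if (!is.null(labels)) SingleCellExperiment::colLabels(sce) <- labels
  sce
}

#' Read/write a ligand-receptor pair database
#'
#' The database is a tab-separated file with header columns `ligand` and
#' `receptor` (an optional `annotation` column is preserved). Rows must be
#' unique and gene ids nonempty.
#'
#' @param db data frame to write.
#' @param path TSV path.
#' @return `readLRDatabase` returns the validated data frame.
#' @export
writeLRDatabase <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLRDatabase
#' @export
readLRDatabase <- function(path) {
  db <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(db))) {
    stop("pair database needs 'ligand' and 'receptor' columns")
  }
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor))) {
    stop("pair database contains empty gene ids")
  }
  if (anyDuplicated(db[, c("ligand", "receptor")])) {
    stop("pair database contains duplicate (ligand, receptor) rows")
  }
  db
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Frames are quantized to the requested bit depth; intensities are assumed
#' to be on `[0, 1]`.
#'
#' @param fs a [FrameStack-class].
#' @param path output TIFF path.
#' @param bitsPerSample 8 (default) or 16.
#' @return Invisibly, the path.
#' @export
writeFrameStack <- function(fs, path, bitsPerSample = 8L) {
  stopifnot(methods::is(fs, "FrameStack"))
  f <- fs@frames
  pages <- lapply(seq_len(dim(f)[1L]), function(t) f[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

#' Read a multi-page TIFF video into a FrameStack
#'
#' Pages are decoded to intensities on `[0, 1]` (8-bit samples are divided
#' by 255, 16-bit by 65535, as done by the TIFF reader); RGB pages are
#' converted to luminance via [toGrayscale()]. All pages must share one
#' shape.
#'
#' @param path TIFF path.
#' @param sourceId identifier for the returned stack (defaults to the file
#'   name).
#' @return A [FrameStack-class].
#' @export
readFrameStack <- function(path, sourceId = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("TIFF pages have mixed shapes")
  }
  d <- dims[[1L]]
  if (length(d) == 3L && d[3L] >= 3L) {
    arr <- array(0, dim = c(length(pages), d[1L], d[2L], 3L))
    for (t in seq_along(pages)) arr[t, , , ] <- pages[[t]][, , 1:3]
    toGrayscale(arr, sourceId = sourceId)
  } else {
    arr <- array(0, dim = c(length(pages), d[1L], d[2L]))
    for (t in seq_along(pages)) {
      arr[t, , ] <- if (length(d) == 3L) pages[[t]][, , 1L] else pages[[t]]
    }
    FrameStack(arr, sourceId = sourceId)
  }
}
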