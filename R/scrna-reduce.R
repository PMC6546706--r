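#' Rank genes by within-bin dispersion z-score
#'
#' Identifies highly variable genes on the mean/dispersion plane of the
#' back-transformed normalized values (`expm1` of the log-normalized matrix):
#' genes are placed in `nBins` equal-frequency bins of mean expression, the
#' log dispersion (variance over mean) is z-scored within each bin to remove
#' the mean-dispersion trend, and genes with `z > zCutoff` are flagged as
#' variable, ranked by z descending with ties broken by gene id.
#'
#' Genes with zero mean or zero dispersion carry no information and receive
#' `z = NA`; a bin whose dispersions are all equal gets `z = 0` throughout
#' (so a constant matrix selects nothing).
#'
#' @param x a `SingleCellExperiment` with a `logcounts` assay, or a
#'   log-normalized genes x cells matrix.
#' @param nBins number of equal-frequency mean-expression bins (default 20;
#'   reduced with a warning when fewer genes than bins are available).
#' @param zCutoff dispersion z-score above which a gene is called variable.
#'
#' @return A data frame (one row per gene, ordered by decreasing z) with
#'   columns `gene`, `mean`, `dispersion`, `bin`, `z`, `selected`.
#' @export
findVariableGenes <- function(x, nBins = 20L, zCutoff = 1) {
  nm <- .logcounts(x)
  e <- expm1(nm)
  n <- ncol(e)
  mu <- Matrix::rowMeans(e)
  v <- (Matrix::rowMeans(e * e) - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  disp[is.finite(disp) & disp <= 0] <- NA_real_
  logDisp <- log(disp)

  genes <- rownames(nm)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(nm)))
  usable <- is.finite(logDisp)
  nBins <- as.integer(nBins)
  if (sum(usable) < nBins) {
    nBins <- max(1L, sum(usable))
    warning("fewer informative genes than bins; using ", nBins, " bins")
  }

  bin <- rep(NA_integer_, length(mu))
  if (any(usable)) {
    r <- rank(mu[usable], ties.method = "first")
    bin[usable] <- as.integer(ceiling(r * nBins / sum(usable)))
  }
  z <- rep(NA_real_, length(mu))
  for (b in seq_len(nBins)) {
    i <- which(bin == b)
    if (!length(i)) next
    m <- mean(logDisp[i])
    s <- stats::sd(logDisp[i])
    z[i] <- if (!is.finite(s) || s == 0) 0 else (logDisp[i] - m) / s
  }

  out <- data.frame(
    gene = genes, mean = mu, dispersion = disp, bin = bin, z = z,
    selected = !is.na(z) & z > zCutoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-replace(out$z, is.na(out$z), -Inf), out$gene), , drop = FALSE]
}

#' Principal component analysis on selected genes
#'
#' Scales each selected gene to mean 0 and unit variance across cells and
#' decomposes the cells x genes matrix by SVD. The decomposition is made
#' deterministic up to machine precision by fixing each loading vector's
#' sign so that its largest-magnitude entry is positive.
#'
#' @param x a `SingleCellExperiment` with `logcounts`, or a log-normalized
#'   genes x cells matrix.
#' @param genes character vector of genes to use (e.g. the variable genes);
#'   defaults to all genes. Genes with zero variance are dropped with a
#'   warning.
#' @param nPCs number of components to keep (default 20; reduced with a
#'   warning when it exceeds the data's rank bound).
#'
#' @return A list of class `ScPCA` with elements `embedding` (cells x PCs
#'   scores), `loadings` (genes x PCs), `varExplained` (fraction per PC over
#'   all `min(genes, cells)` components), `scaled` (the scaled genes x cells
#'   matrix, reused by [jackstrawSelectPCs()]) and `nPCs`.
#' @export
runPCA <- function(x, genes = NULL, nPCs = 20L) {
  nm <- .logcounts(x)
  nm <- as.matrix(nm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(nm))
    if (length(missing)) {
      stop("genes not in the matrix: ", paste(utils::head(missing, 3L), collapse = ", "))
    }
    nm <- nm[genes, , drop = FALSE]
  }
  mu <- rowMeans(nm)
  s <- apply(nm, 1L, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) dropped before PCA")
    nm <- nm[!flat, , drop = FALSE]
    mu <- mu[!flat]
    s <- s[!flat]
  }
  if (nrow(nm) < 2L) stop("fewer than two informative genes for PCA")
  scaled <- (nm - mu) / s

  maxPCs <- min(dim(scaled))
  nPCs <- as.integer(nPCs)
  if (nPCs > maxPCs) {
    warning("'nPCs' reduced to the rank bound ", maxPCs)
    nPCs <- maxPCs
  }
  sv <- svd(t(scaled))
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(sv$v))) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  embedding <- sv$u[, seq_len(nPCs), drop = FALSE] %*%
    diag(sv$d[seq_len(nPCs)], nPCs)
  loadings <- sv$v[, seq_len(nPCs), drop = FALSE]
  dimnames(embedding) <- list(colnames(scaled), paste0("PC", seq_len(nPCs)))
  dimnames(loadings) <- list(rownames(scaled), paste0("PC", seq_len(nPCs)))
  structure(
    list(
      embedding = embedding, loadings = loadings,
      varExplained = sv$d^2 / sum(sv$d^2),
      scaled = scaled, nPCs = nPCs
    ),
    class = "ScPCA"
  )
}

#' @export
print.ScPCA <- function(x, ...) {
  cat(sprintf(
    "PCA: %d cells x %d genes, %d PCs kept (PC1 %.1f%% variance)\n",
    nrow(x$embedding), nrow(x$loadings), x$nPCs, 100 * x$varExplained[1L]
  ))
  invisible(x)
}

#' Jackstraw significance of principal components
#'
#' Permutation test for which PCs carry real structure. In each replicate a
#' small random fraction of genes is permuted across cells (destroying their
#' covariation while preserving their marginal distribution) and the PCA is
#' recomputed with the permuted genes included. Each permuted gene is then
#' located within that replicate's full absolute-loading distribution as a
#' rank quantile in `(0, 1]`. When a PC reflects real covariation, permuted
#' (signal-destroyed) genes sink to the bottom of its loading distribution;
#' when it is noise, a permuted gene is exchangeable with every other gene
#' and its quantile is uniform. The per-PC p-value is a one-sided exact
#' binomial test of whether permuted-gene quantiles fall at or below
#' `propThreshold` more often than `propThreshold` of the time. PCs with
#' p below `alpha` are reported as significant.
#'
#' The quantile is computed within each replicate rather than against a
#' pooled observed-versus-null comparison: eigenvector loadings of all genes
#' share one realization of the component (its concentration and singular
#' value), and within-replicate ranks are immune to that common mode, which
#' keeps the test calibrated at very small `alpha`.
#'
#' @param pca an `ScPCA` object from [runPCA()].
#' @param alpha PC-level significance threshold (default 6.02e-5). A value
#'   of 1 or more is treated as vacuous and returns all tested PCs.
#' @param nReplicates number of permutation replicates (default 100; fewer
#'   than 10 triggers a warning that the quantile resolution is too coarse
#'   for small `alpha`).
#' @param permutedFraction fraction of genes permuted per replicate
#'   (default 0.01; always at least one gene). Small gene panels benefit
#'   from a larger fraction, which increases the number of null draws.
#' @param nPCsTested number of leading PCs to test (default 20, capped at
#'   the PCs available).
#' @param propThreshold bottom-quantile cutoff counted by the binomial test
#'   (default 0.1, the bottom decile of each replicate's loadings).
#' @param seed integer seed for the permutation stream.
#'
#' @return A list with `significant` (indices of significant PCs, in order),
#'   `pValues` (per tested PC), `alpha` and the permutation settings.
#' @export
jackstrawSelectPCs <- function(pca, alpha = 6.02e-5, nReplicates = 100L,
                               permutedFraction = 0.01, nPCsTested = 20L,
                               propThreshold = 0.1, seed = 1L) {
  stopifnot(inherits(pca, "ScPCA"))
  if (alpha <= 0) stop("'alpha' must be positive")
  if (permutedFraction <= 0 || permutedFraction > 1) {
    stop("'permutedFraction' must lie in (0, 1]")
  }
  if (propThreshold <= 0 || propThreshold >= 1) {
    stop("'propThreshold' must lie in (0, 1)")
  }
  if (nReplicates < 10L) {
    warning("fewer than 10 replicates: permutation quantile resolution is ",
            "coarser than typical 'alpha' thresholds")
  }
  scaled <- pca$scaled
  nGenes <- nrow(scaled)
  nCells <- ncol(scaled)
  nPCsTested <- min(as.integer(nPCsTested), pca$nPCs)
  nPerm <- max(1L, floor(permutedFraction * nGenes))

  quantiles <- withSeed(seed, {
    acc <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      idx <- sample.int(nGenes, nPerm)
      perm <- scaled
      for (g in idx) perm[g, ] <- perm[g, sample.int(nCells)]
      sv <- svd(t(perm), nu = 0L, nv = nPCsTested)
      ranks <- apply(abs(sv$v), 2L, rank)
      acc[[r]] <- ranks[idx, , drop = FALSE] / nGenes
    }
    do.call(rbind, acc)
  })

  nDraws <- nrow(quantiles)
  pPC <- vapply(seq_len(nPCsTested), function(j) {
    low <- sum(quantiles[, j] <= propThreshold)
    stats::binom.test(low, nDraws, p = propThreshold,
                      alternative = "greater")$p.value
  }, numeric(1))
  names(pPC) <- paste0("PC", seq_len(nPCsTested))

  significant <- if (alpha >= 1) seq_len(nPCsTested) else which(pPC < alpha)
  list(
    significant = unname(significant), pValues = pPC, alpha = alpha,
    nReplicates = nReplicates, permutedFraction = permutedFraction,
    propThreshold = propThreshold
  )
}
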