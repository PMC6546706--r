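# Independent brute-force oracles used across the suite. These deliberately
# use naive loops so they share no code path with the implementation.

# per-pixel mean |I(t+lag) - I(t)| by explicit triple loop
oracleHeat <- function(f, lag = 4L, method = "sliding") {
  nT <- dim(f)[1L]
  starts <- if (method == "sliding") seq_len(nT - lag) else
    seq.int(1L, nT - lag, by = lag)
  h <- matrix(0, dim(f)[2L], dim(f)[3L])
  for (y in seq_len(dim(f)[2L])) {
    for (x in seq_len(dim(f)[3L])) {
      s <- 0
      for (t in starts) s <- s + abs(f[t + lag, y, x] - f[t, y, x])
      h[y, x] <- s / length(starts)
    }
  }
  h
}

# element-wise luminance by explicit loops
oracleGray <- function(a) {
  d <- dim(a)
  g <- array(0, d[1:3])
  w <- c(0.299, 0.587, 0.114)
  for (t in seq_len(d[1L])) {
    for (y in seq_len(d[2L])) {
      for (x in seq_len(d[3L])) {
        g[t, y, x] <- sum(w * a[t, y, x, ])
      }
    }
  }
  g
}

# classic between/within mean-square ratio
oracleAnovaF <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# per-cluster mean / detection by explicit loops
oracleProfile <- function(nm, labels) {
  labels <- factor(labels)
  means <- det <- matrix(0, nrow(nm), nlevels(labels),
                         dimnames = list(rownames(nm), levels(labels)))
  for (k in levels(labels)) {
    for (g in seq_len(nrow(nm))) {
      v <- nm[g, labels == k]
      means[g, k] <- mean(v)
      det[g, k] <- mean(v > 0)
    }
  }
  list(means = means, detection = det)
}

# exhaustive interaction counting over all db rows and cluster pairs
oracleCounts <- function(callsMatrix, db, senders, receivers) {
  out <- matrix(0L, length(senders), length(receivers),
                dimnames = list(senders, receivers))
  for (i in seq_len(nrow(db))) {
    l <- db$ligand[i]
    r <- db$receptor[i]
    if (!(l %in% rownames(callsMatrix)) || !(r %in% rownames(callsMatrix))) next
    for (s in senders) {
      for (rc in receivers) {
        if (callsMatrix[l, s] && callsMatrix[r, rc]) {
          out[s, rc] <- out[s, rc] + 1L
        }
      }
    }
  }
  out
}

randStack <- function(nT, h, w, seed) {
  set.seed(seed)
  array(runif(nT * h * w), dim = c(nT, h, w))
}

ari <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}

# the hand-enumerated 6-gene x 5-cell QC toy matrix
qcToyCounts <- function() {
  m <- rbind(
    g1 = c(2, 2, 2, 0, 0), # count > 1 in 3 cells -> kept
    g2 = c(2, 2, 0, 0, 0), # only 2 cells -> dropped
    g3 = c(1, 1, 1, 1, 1), # 1 is not > 1 -> dropped
    g4 = c(5, 0, 3, 2, 9), # kept
    g5 = c(0, 0, 0, 0, 0), # dropped
    g6 = c(2, 3, 2, 2, 1)  # kept
  )
  colnames(m) <- paste0("c", 1:5)
  m
}

makeSCE <- function(counts, labels = NULL) {
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix"))
  )
  if (!is.null(labels)) SingleCellExperiment::colLabels(sce) <- factor(labels)
  sce
}
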