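#' Construct a FrameStack
#'
#' @param frames numeric `T x H x W` array with values in `[0, 1]`.
#' @param frameInterval seconds between frames, if known.
#' @param sourceId identifier carried through heat maps and score tables.
#'
#' @return A [FrameStack-class] object.
#' @export
FrameStack <- function(frames, frameInterval = NA_real_, sourceId = "unknown") {
  new("FrameStack",
    frames = frames, frameInterval = as.numeric(frameInterval),
    sourceId = as.character(sourceId)
  )
}

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a contracting-organoid brightfield video
#'
#' Renders a centered bright disc on a darker background whose radius
#' oscillates as `baseRadius * (1 + amplitude * sin(2 * pi * t / period))`
#' (frames indexed from 0), emulating the periodic radial contraction of a
#' muscle organoid recorded under a brightfield microscope. The disc edge is
#' anti-aliased with a one-pixel linear ramp so sub-pixel radius changes move
#' pixel values smoothly; optional i.i.d. Gaussian pixel noise is added after
#' rendering and clipped to `[0, 1]`, mimicking camera saturation.
#'
#' The generator is a pure function of its parameters: identical parameters
#' and seed give a bit-identical stack, and the caller's RNG state is left
#' untouched.
#'
#' @param nFrames number of frames (at least 5).
#' @param height,width frame size in pixels.
#' @param baseRadius resting disc radius in pixels; the dilated radius
#'   `baseRadius * (1 + amplitude)` must fit inside the frame.
#' @param amplitude relative contraction amplitude, `0 <= amplitude < 1`.
#' @param period frames per contraction cycle.
#' @param noiseSigma standard deviation of additive Gaussian pixel noise,
#'   in intensity units.
#' @param fg,bg foreground (disc) and background intensities in `[0, 1]`.
#' @param seed integer seed for the noise stream.
#' @param sourceId identifier stored in the returned stack.
#'
#' @return A [FrameStack-class].
#' @examples
#' fs <- simulateContractionVideo(nFrames = 20, amplitude = 0.2, noiseSigma = 0)
#' fs
#' @export
simulateContractionVideo <- function(nFrames = 60L, height = 128L, width = 128L,
                                     baseRadius = 40, amplitude = 0.1,
                                     period = 20, noiseSigma = 0.01,
                                     fg = 0.8, bg = 0.2, seed = 1L,
                                     sourceId = "synthetic-video") {
  if (nFrames < 5L) {
    stop("'nFrames' must be at least 5 so that one lag-4 frame pair exists")
  }
  if (height < 1L || width < 1L || baseRadius <= 0) {
    stop("frame dimensions and 'baseRadius' must be positive")
  }
  if (amplitude < 0 || amplitude >= 1) {
    stop("'amplitude' must satisfy 0 <= amplitude < 1")
  }
  if (period <= 0) stop("'period' must be positive")
  if (noiseSigma < 0) stop("'noiseSigma' must be nonnegative")
  if (any(c(fg, bg) < 0) || any(c(fg, bg) > 1)) {
    stop("'fg' and 'bg' intensities must lie in [0, 1]")
  }
  rMax <- baseRadius * (1 + amplitude)
  if (2 * (rMax + 0.5) > min(height, width)) {
    stop(sprintf(
      "dilated disc (radius %.1f px) exceeds the %d x %d frame",
      rMax, height, width
    ))
  }

  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  d <- sqrt(outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`))

  out <- array(0, dim = c(nFrames, height, width))
  for (t in seq_len(nFrames)) {
    # sinpi() keeps the radius exactly periodic: frame 0 == frame `period`
    r <- baseRadius * (1 + amplitude * sinpi(2 * (t - 1) / period))
    coverage <- pmin(1, pmax(0, r - d + 0.5))
    out[t, , ] <- bg + (fg - bg) * coverage
  }
  if (noiseSigma > 0) {
    out <- out + withSeed(seed, stats::rnorm(length(out), sd = noiseSigma))
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  FrameStack(out, sourceId = sourceId)
}

#' Simulate a clustered single-cell count matrix with planted ground truth
#'
#' Draws a genes x cells matrix of negative-binomial counts organized in
#' `nClusters` cell populations, emulating a small single-cell RNA-seq run on
#' a heterogeneous muscle-derived cell mixture. Per-gene baseline means are
#' drawn log-normally around `baselineMean` (the median) so that gene-level
#' QC and variable-gene selection act on a realistic abundance spread. Three
#' gene classes carry signal:
#'
#' * marker genes: `markersPerCluster` genes per cluster whose mean is
#'   inflated by `exp(markerLogFC)` in their cluster;
#' * ligand/receptor channel genes (`lrChannels`): expressed only in their
#'   planted cluster (ligand in the sender, receptor in the receiver, mean
#'   `baselineMean * exp(markerLogFC)`), silent elsewhere;
#' * a silent tail (`silentFraction` of genes) with mean 0 everywhere, the
#'   pool from which decoy database pairs are drawn.
#'
#' The negative binomial is parameterized by mean `mu` and dispersion `phi`
#' with variance `mu + mu^2 * phi` (`phi = 0` reduces to Poisson).
#'
#' @param nClusters number of cell clusters (>= 1).
#' @param cellsPerCluster cells per cluster (scalar or length-`nClusters`).
#' @param nGenes total number of genes.
#' @param markersPerCluster planted marker genes per cluster.
#' @param markerLogFC natural-log fold change of marker means in their
#'   cluster.
#' @param nbDispersion negative-binomial dispersion `phi` (>= 0).
#' @param baselineMean median baseline mean count per gene.
#' @param baselineSdLog log-scale spread of per-gene baseline means
#'   (0 makes all baselines equal to `baselineMean`).
#' @param lrChannels `NULL`, or a data frame with columns `ligand`,
#'   `receptor` (gene ids), `sender`, `receiver` (cluster ids in
#'   `1:nClusters`) listing planted signaling channels. Channel genes must
#'   be disjoint from marker genes.
#' @param silentFraction fraction of genes left silent (mean 0).
#' @param seed integer seed.
#'
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (sparse), `colData(.)$cluster` as a factor of generating labels,
#'   and `metadata(.)$truth` holding the planted ground truth: `markers`
#'   (gene/cluster table), `channels`, `trueMeans` (genes x clusters),
#'   `silentGenes` and `expressedGenes`.
#' @examples
#' sce <- simulateExpression(nClusters = 3, cellsPerCluster = 50, nGenes = 200)
#' table(SingleCellExperiment::colLabels(sce))
#' @export
simulateExpression <- function(nClusters = 4L, cellsPerCluster = 140L,
                               nGenes = 800L, markersPerCluster = 20L,
                               markerLogFC = 1.0, nbDispersion = 0.3,
                               baselineMean = 5, baselineSdLog = 1,
                               lrChannels = NULL, silentFraction = 0.1,
                               seed = 1L) {
  if (nClusters < 1L) stop("'nClusters' must be at least 1")
  if (nGenes < 1L) stop("'nGenes' must be at least 1")
  if (any(cellsPerCluster < 1L)) stop("'cellsPerCluster' must be positive")
  if (nbDispersion < 0) stop("'nbDispersion' must be nonnegative")
  if (baselineMean <= 0) stop("'baselineMean' must be positive")
  cellsPerCluster <- rep_len(as.integer(cellsPerCluster), nClusters)

  genes <- sprintf("G%04d", seq_len(nGenes))
  nSilent <- ceiling(silentFraction * nGenes)
  silentGenes <- if (nSilent > 0) utils::tail(genes, nSilent) else character()
  nMarkers <- nClusters * markersPerCluster
  if (nMarkers > nGenes - nSilent) {
    stop("too many marker genes for the requested gene count")
  }
  markerGenes <- genes[seq_len(nMarkers)]
  markerCluster <- rep(seq_len(nClusters), each = markersPerCluster)

  channelGenes <- character()
  if (!is.null(lrChannels)) {
    lrChannels <- as.data.frame(lrChannels)
    need <- c("ligand", "receptor", "sender", "receiver")
    if (!all(need %in% names(lrChannels))) {
      stop("'lrChannels' needs columns ligand, receptor, sender, receiver")
    }
    channelGenes <- unique(c(lrChannels$ligand, lrChannels$receptor))
    if (!all(channelGenes %in% genes)) {
      stop("planted channel genes must be drawn from the simulated gene ids")
    }
    if (any(channelGenes %in% markerGenes)) {
      stop("planted ligand/receptor genes must be disjoint from marker genes")
    }
    badCl <- c(lrChannels$sender, lrChannels$receiver)
    if (any(badCl < 1 | badCl > nClusters)) {
      stop("channel sender/receiver clusters must lie in 1:nClusters")
    }
  }

  out <- withSeed(seed, {
    baseMean <- baselineMean *
      exp(stats::rnorm(nGenes, mean = 0, sd = baselineSdLog))
    baseMean[genes %in% silentGenes] <- 0

    mu <- matrix(baseMean, nrow = nGenes, ncol = nClusters,
                 dimnames = list(genes, paste0("cluster", seq_len(nClusters))))
    idx <- cbind(match(markerGenes, genes), markerCluster)
    mu[idx] <- mu[idx] * exp(markerLogFC)
    if (length(channelGenes)) {
      mu[channelGenes, ] <- 0
      lrMean <- baselineMean * exp(markerLogFC)
      for (i in seq_len(nrow(lrChannels))) {
        mu[lrChannels$ligand[i], lrChannels$sender[i]] <- lrMean
        mu[lrChannels$receptor[i], lrChannels$receiver[i]] <- lrMean
      }
    }

    counts <- matrix(0L, nrow = nGenes, ncol = sum(cellsPerCluster))
    labels <- integer(0)
    col0 <- 0L
    for (k in seq_len(nClusters)) {
      nc <- cellsPerCluster[k]
      draw <- if (nbDispersion > 0) {
        stats::rnbinom(nGenes * nc, mu = mu[, k], size = 1 / nbDispersion)
      } else {
        stats::rpois(nGenes * nc, lambda = mu[, k])
      }
      counts[, col0 + seq_len(nc)] <- draw
      labels <- c(labels, rep.int(k, nc))
      col0 <- col0 + nc
    }
    list(counts = counts, labels = labels, mu = mu)
  })

  cells <- sprintf("C%04d", seq_len(ncol(out$counts)))
  dimnames(out$counts) <- list(genes, cells)
  truth <- list(
    markers = data.frame(gene = markerGenes, cluster = markerCluster,
                         stringsAsFactors = FALSE),
    channels = lrChannels,
    trueMeans = out$mu,
    silentGenes = setdiff(silentGenes, channelGenes),
    expressedGenes = genes[rowSums(out$mu) > 0]
  )
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(out$counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(
      cluster = factor(out$labels, levels = seq_len(nClusters)),
      row.names = cells
    )
  )
  SingleCellExperiment::colLabels(sce) <- sce$cluster
  S4Vectors::metadata(sce)$truth <- truth
  S4Vectors::metadata(sce)$provenance <- "simulateExpression"
  sce
}

#' Simulate a ligand-receptor pair database
#'
#' Combines a set of planted (truly signaling) ligand-receptor pairs with
#' decoy pairs drawn from genes that are expressed nowhere, emulating the
#' curated pair lists used by receptor-ligand pairing screens: most database
#' entries are irrelevant to any given dataset.
#'
#' @param planted data frame with columns `ligand` and `receptor` (e.g. the
#'   `channels` component of [simulateExpression()] truth). Duplicate rows
#'   are rejected.
#' @param nDecoys number of decoy pairs to add.
#' @param decoyGenes character pool of gene ids that are not expressed in
#'   any cluster; decoy pairs are sampled from it. Must be disjoint from the
#'   planted genes.
#' @param seed integer seed.
#'
#' @return A data frame with columns `ligand`, `receptor`, `annotation`
#'   (`"planted"` or `"decoy"`), with unique (ligand, receptor) rows.
#' @export
simulateLRDatabase <- function(planted, nDecoys = 0L, decoyGenes = character(),
                               seed = 1L) {
  planted <- as.data.frame(planted)[, c("ligand", "receptor")]
  if (anyDuplicated(planted)) {
    stop("duplicate (ligand, receptor) rows in the planted pair list")
  }
  plantedGenes <- unique(unlist(planted))
  if (any(decoyGenes %in% plantedGenes)) {
    stop("'decoyGenes' must be disjoint from planted pair genes")
  }
  db <- data.frame(planted, annotation = rep("planted", nrow(planted)),
                   stringsAsFactors = FALSE)
  if (nDecoys > 0L) {
    if (length(decoyGenes) < 2L) {
      stop("at least two decoy genes are required to draw decoy pairs")
    }
    decoys <- withSeed(seed, {
      seen <- paste(db$ligand, db$receptor)
      lig <- character(nDecoys)
      rec <- character(nDecoys)
      i <- 1L
      guard <- 0L
      while (i <= nDecoys) {
        cand <- sample(decoyGenes, 2L)
        key <- paste(cand[1L], cand[2L])
        if (!key %in% seen) {
          lig[i] <- cand[1L]
          rec[i] <- cand[2L]
          seen <- c(seen, key)
          i <- i + 1L
        }
        guard <- guard + 1L
        if (guard > 1000L * nDecoys) {
          stop("decoy gene pool too small for the requested decoy count")
        }
      }
      data.frame(ligand = lig, receptor = rec,
                 annotation = rep("decoy", nDecoys),
                 stringsAsFactors = FALSE)
    })
    db <- rbind(db, decoys)
  }
  rownames(db) <- NULL
  db
}
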