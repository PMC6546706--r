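.configDefaults <- function() {
  list(
    seed = 1L,
    synthetic = list(
      expression = list(
        nClusters = 4L, cellsPerCluster = 140L, nGenes = 800L,
        markersPerCluster = 20L, markerLogFC = 1.0, nbDispersion = 0.3,
        baselineMean = 5, baselineSdLog = 1, silentFraction = 0.1,
        nChannels = 3L, nDecoys = 10L
      ),
      video = list(
        nFrames = 60L, height = 128L, width = 128L, baseRadius = 40,
        period = 20, noiseSigma = 0.01, fg = 0.8, bg = 0.2,
        videosPerGroup = 3L,
        amplitudes = list(MR = 0.20, TM = 0.10, TR = 0.02, M = 0.05, R = 0.01)
      )
    ),
    qc = list(minCount = 1, minCells = 3L, minGenes = 1000L),
    normalize = list(scaleFactor = 1e4),
    hvg = list(nBins = 20L, zCutoff = 1),
    pca = list(nPCs = 20L),
    jackstraw = list(
      alpha = 6.02e-5, nReplicates = 100L, permutedFraction = 0.01,
      nPCsTested = 20L, propThreshold = 0.1
    ),
    cluster = list(resolution = 0.8, kNeighbors = 20L),
    markers = list(logfcThreshold = 0.25),
    presence = list(minDetection = 0.1, minMean = 0.25),
    connectivity = list(topK = 50L),
    moveheat = list(lag = 4L, method = "sliding")
  )
}

.mergeConfig <- function(defaults, overrides, path = "") {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) stop("config section '", path, "' must be a list")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(overrides)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && k != "amplitudes") {
      .mergeConfig(defaults[[k]], overrides[[k]], paste0(path, k, "$"))
    } else {
      overrides[[k]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Returns the full nested parameter set of the end-to-end pipeline with the
#' documented stage defaults, selectively overridden by named sections
#' passed as arguments. Unknown keys are rejected rather than ignored, so a
#' typo cannot silently change a threshold.
#'
#' @param ... named config sections to override, e.g.
#'   `pipelineConfig(seed = 7, qc = list(minGenes = 200))`.
#' @return A list of class `PipelineConfig`.
#' @seealso [syntheticPipelineConfig()], [runPipeline()]
#' @export
pipelineConfig <- function(...) {
  overrides <- list(...)
  cfg <- .mergeConfig(.configDefaults(), overrides)
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Pipeline configuration matched to the synthetic generators
#'
#' Same as [pipelineConfig()] but with two boundaries rescaled to the
#' simulated gene panel: the detected-genes cell QC rule (>= 1000 by
#' default, meant for genome-wide libraries) is set to a quarter of the
#' expressed genes, and the jackstraw permuted-gene fraction is raised to
#' 0.1 so that a panel of a few hundred genes still yields several permuted
#' genes (hence adequate quantile resolution) per replicate.
#'
#' @param seed global pipeline seed.
#' @param ... further overrides, as in [pipelineConfig()].
#' @return A `PipelineConfig`.
#' @export
syntheticPipelineConfig <- function(seed = 1L, ...) {
  cfg <- pipelineConfig(seed = as.integer(seed), ...)
  nExpressed <- with(cfg$synthetic$expression,
                     nGenes - ceiling(silentFraction * nGenes))
  over <- list(...)
  if (is.null(over$qc$minGenes)) {
    cfg$qc$minGenes <- as.integer(nExpressed / 4)
  }
  if (is.null(over$jackstraw$permutedFraction)) {
    cfg$jackstraw$permutedFraction <- 0.1
  }
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' The YAML round-trips losslessly; unknown keys in the file are rejected
#' on read.
#'
#' @param cfg a `PipelineConfig`.
#' @param path YAML file path.
#' @return `readPipelineConfig` returns a validated `PipelineConfig`.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(.mergeConfig(.configDefaults(), raw),
            class = c("PipelineConfig", "list"))
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig (seed ", x$seed, "):\n", sep = "")
  for (s in setdiff(names(x), "seed")) {
    cat("  ", s, ": ",
        paste(names(unlist(x[[s]])), unlist(x[[s]]),
              sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Default planted signaling channels for the synthetic run: ligands from the
# non-marker background region, senders cycling over the non-MPC clusters,
# all receptors read by cluster 2 (the myogenic receiver).
.defaultChannels <- function(e) {
  genes <- sprintf("G%04d", seq_len(e$nGenes))
  nSilent <- ceiling(e$silentFraction * e$nGenes)
  lastExpressed <- e$nGenes - nSilent
  take <- lastExpressed - seq_len(2L * e$nChannels) + 1L
  if (min(take) <= e$nClusters * e$markersPerCluster) {
    stop("gene panel too small to place the planted signaling channels")
  }
  receiver <- min(2L, e$nClusters)
  senders <- setdiff(seq_len(e$nClusters), receiver)
  if (!length(senders)) senders <- receiver
  data.frame(
    ligand = genes[take[seq_len(e$nChannels) * 2L - 1L]],
    receptor = genes[take[seq_len(e$nChannels) * 2L]],
    sender = rep_len(senders, e$nChannels),
    receiver = receiver,
    stringsAsFactors = FALSE
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes, in order: synthetic data generation (expression, pair database,
#' contraction videos), gene and cell QC, log-normalization, variable-gene
#' selection, PCA, jackstraw PC selection, graph clustering, marker
#' detection, the ligand-receptor connectivity screen, and contraction
#' scoring with a group ANOVA. Every stage writes its artifacts under
#' `outDir` and the run closes with a manifest recording the config, package
#' version, per-file MD5 checksums and per-stage record counts. Re-running
#' with an identical config reproduces identical artifact checksums.
#'
#' A stage failure aborts the run with the failing stage named; artifacts
#' already written are retained and flagged in `manifest_partial.json`.
#'
#' @param config a `PipelineConfig` (default: [syntheticPipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#'
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
runPipeline <- function(config = syntheticPipelineConfig(),
                        outDir = tempfile("myoconnect_run_"),
                        quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  counts <- list()
  addFile <- function(p) files <<- unique(c(files, p))

  finish <- function(status, failedStage = NULL) {
    manifest <- list(
      package = "MyoConnect",
      version = as.character(utils::packageVersion("MyoConnect")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      status = status,
      failed_stage = failedStage,
      config = unclass(config),
      records = counts,
      checksums = as.list(tools::md5sum(files[file.exists(files)]))
    )
    names(manifest$checksums) <-
      basename(names(manifest$checksums))
    out <- file.path(outDir, if (is.null(failedStage)) "manifest.json"
                     else "manifest_partial.json")
    jsonlite::write_json(manifest, out, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    manifest
  }

  result <- tryCatch({
    e <- config$synthetic$expression
    say("stage synth_expression: ", e$nClusters, " clusters x ",
        e$cellsPerCluster, " cells, ", e$nGenes, " genes")
    channels <- .defaultChannels(e)
    sce <- .stage("synth_expression", simulateExpression(
      nClusters = e$nClusters, cellsPerCluster = e$cellsPerCluster,
      nGenes = e$nGenes, markersPerCluster = e$markersPerCluster,
      markerLogFC = e$markerLogFC, nbDispersion = e$nbDispersion,
      baselineMean = e$baselineMean, baselineSdLog = e$baselineSdLog,
      lrChannels = channels, silentFraction = e$silentFraction,
      seed = config$seed
    ))
    truth <- S4Vectors::metadata(sce)$truth
    rawDir <- file.path(outDir, "raw")
    addFile(writeExpression(sce, rawDir))
    truthPath <- file.path(outDir, "truth.json")
    jsonlite::write_json(
      list(markers = truth$markers, channels = truth$channels,
           silentGenes = truth$silentGenes),
      truthPath, auto_unbox = TRUE, digits = NA
    )
    addFile(truthPath)

    db <- .stage("synth_lr_database", simulateLRDatabase(
      channels[, c("ligand", "receptor")], nDecoys = e$nDecoys,
      decoyGenes = truth$silentGenes, seed = config$seed + 3L
    ))
    dbPath <- file.path(outDir, "lr_pairs.tsv")
    addFile(writeLRDatabase(db, dbPath))
    counts$lr_database <- nrow(db)

    say("stage qc: gene filter (count > ", config$qc$minCount, " in >= ",
        config$qc$minCells, " cells), cell filter (>= ",
        config$qc$minGenes, " genes)")
    before <- dim(sce)
    filt <- .stage("qc", {
      x <- filterGenes(sce, config$qc$minCount, config$qc$minCells)
      filterCells(x, config$qc$minGenes)
    })
    counts$qc <- list(
      genes_before = before[1L], cells_before = before[2L],
      genes_after = nrow(filt), cells_after = ncol(filt)
    )
    say("  ", before[1L], " -> ", nrow(filt), " genes; ",
        before[2L], " -> ", ncol(filt), " cells passed the filter")
    qcPath <- file.path(outDir, "qc_report.json")
    jsonlite::write_json(counts$qc, qcPath, auto_unbox = TRUE, digits = NA)
    addFile(qcPath)

    filt <- .stage("normalize",
                   logNormalize(filt, config$normalize$scaleFactor))
    normDir <- file.path(outDir, "normalized")
    addFile(writeExpression(filt, normDir, assay = "logcounts"))

    hvg <- .stage("hvg", findVariableGenes(filt, config$hvg$nBins,
                                           config$hvg$zCutoff))
    varGenes <- hvg$gene[hvg$selected]
    counts$variable_genes <- length(varGenes)
    say("stage hvg: ", length(varGenes), " variable genes")
    hvgPath <- file.path(outDir, "variable_genes.tsv")
    utils::write.table(hvg, hvgPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addFile(hvgPath)

    pca <- .stage("pca", runPCA(filt, varGenes, config$pca$nPCs))
    js <- .stage("jackstraw", jackstrawSelectPCs(
      pca, alpha = config$jackstraw$alpha,
      nReplicates = config$jackstraw$nReplicates,
      permutedFraction = config$jackstraw$permutedFraction,
      nPCsTested = config$jackstraw$nPCsTested,
      propThreshold = config$jackstraw$propThreshold,
      seed = config$seed + 1L
    ))
    counts$significant_pcs <- length(js$significant)
    say("stage jackstraw: ", length(js$significant),
        " significant PCs at alpha ", config$jackstraw$alpha)
    jsPath <- file.path(outDir, "jackstraw.json")
    jsonlite::write_json(
      list(significant = js$significant, pValues = as.list(js$pValues),
           alpha = js$alpha),
      jsPath, auto_unbox = TRUE, digits = NA
    )
    addFile(jsPath)

    usePCs <- if (length(js$significant)) max(js$significant) else
      min(10L, pca$nPCs)
    labels <- .stage("cluster", clusterCells(
      pca, nPCsUsed = usePCs, resolution = config$cluster$resolution,
      kNeighbors = config$cluster$kNeighbors, seed = config$seed + 2L
    ))
    counts$clusters <- nlevels(droplevels(labels))
    say("stage cluster: ", counts$clusters, " clusters")
    labPath <- file.path(outDir, "cluster_labels.tsv")
    utils::write.table(
      data.frame(cell = names(labels), cluster = as.character(labels)),
      labPath, sep = "\t", quote = FALSE, row.names = FALSE
    )
    addFile(labPath)

    markers <- .stage("markers", findMarkers(
      filt, labels, config$markers$logfcThreshold
    ))
    counts$markers <- nrow(markers)
    say("stage markers: ", nrow(markers), " marker rows")
    mkPath <- file.path(outDir, "markers.csv")
    utils::write.csv(markers, mkPath, row.names = FALSE)
    addFile(mkPath)

    # the connectivity screen is run on the generating labels so planted
    # channels are identifiable sender -> receiver
    prof <- .stage("connectivity", buildClusterProfile(filt))
    calls <- callPresence(prof, config$presence$minDetection,
                          config$presence$minMean)
    imap <- countInteractions(calls, db)
    counts$interactions_total <- sum(interactionCounts(imap))
    counts$pairs_skipped <- nrow(skippedPairs(imap))
    say("stage connectivity: ", counts$interactions_total,
        " interactions, ", counts$pairs_skipped, " pairs skipped")
    meta <- renderInteractionHeatmap(imap, file.path(outDir, "interactions"))
    addFile(file.path(outDir, c("interactions_counts.csv",
                                "interactions.png", "interactions.json")))
    contrib <- do.call(rbind, lapply(names(contributingPairs(imap)), function(k) {
      cp <- contributingPairs(imap)[[k]]
      if (!nrow(cp)) return(NULL)
      data.frame(pair = k, cp, stringsAsFactors = FALSE)
    }))
    ctPath <- file.path(outDir, "contributing_pairs.csv")
    utils::write.csv(
      if (is.null(contrib)) data.frame(pair = character(), ligand = character(),
                                       receptor = character()) else contrib,
      ctPath, row.names = FALSE
    )
    addFile(ctPath)
    skPath <- file.path(outDir, "skipped_pairs.csv")
    utils::write.csv(skippedPairs(imap), skPath, row.names = FALSE)
    addFile(skPath)

    pairings <- scorePairings(prof, db)
    top <- topPairings(pairings, config$connectivity$topK)
    rkPath <- file.path(outDir, "ranked_pairings.csv")
    utils::write.csv(pairings, rkPath, row.names = FALSE)
    tpPath <- file.path(outDir, "top_pairings.csv")
    utils::write.csv(top, tpPath, row.names = FALSE)
    addFile(c(rkPath, tpPath))
    counts$ranked_pairings <- nrow(pairings)

    v <- config$synthetic$video
    say("stage moveheat: ", length(v$amplitudes), " groups x ",
        v$videosPerGroup, " videos")
    scoreRows <- list()
    vidDir <- file.path(outDir, "videos")
    if (!dir.exists(vidDir)) dir.create(vidDir)
    iSeed <- config$seed + 10L
    for (grp in names(v$amplitudes)) {
      for (rep in seq_len(v$videosPerGroup)) {
        id <- sprintf("%s_%d", grp, rep)
        fs <- .stage("moveheat", simulateContractionVideo(
          nFrames = v$nFrames, height = v$height, width = v$width,
          baseRadius = v$baseRadius, amplitude = v$amplitudes[[grp]],
          period = v$period, noiseSigma = v$noiseSigma,
          fg = v$fg, bg = v$bg, seed = iSeed, sourceId = id
        ))
        iSeed <- iSeed + 1L
        tifPath <- file.path(vidDir, paste0(id, ".tiff"))
        addFile(writeFrameStack(fs, tifPath))
        hm <- computeHeatMap(fs, lag = config$moveheat$lag,
                             method = config$moveheat$method)
        hmPath <- file.path(vidDir, paste0(id, "_heat.png"))
        renderHeatImage(hm, hmPath)
        addFile(c(hmPath, paste0(hmPath, ".json")))
        scoreRows[[id]] <- contractionScore(hm, group = grp)
      }
    }
    scores <- do.call(rbind, scoreRows)
    scPath <- file.path(outDir, "contraction_scores.csv")
    utils::write.csv(scores, scPath, row.names = FALSE)
    addFile(scPath)
    cmp <- .stage("moveheat", compareGroups(scores))
    anPath <- file.path(outDir, "contraction_anova.csv")
    utils::write.csv(
      cbind(cmp$anova[rep(1L, nrow(cmp$groups)), ], cmp$groups),
      anPath, row.names = FALSE
    )
    addFile(anPath)
    counts$videos <- nrow(scores)
    counts$anova_p <- cmp$anova$p

    finish("ok")
  }, error = function(e) {
    finish("failed", failedStage = sub("^stage '([^']+)'.*$", "\\1",
                                       conditionMessage(e)))
    stop(e)
  })
  say("run complete: ", outDir)
  invisible(result)
}
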