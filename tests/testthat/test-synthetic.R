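test_that("video generator is deterministic and still without motion or noise", {
  a <- simulateContractionVideo(nFrames = 8, amplitude = 0, noiseSigma = 0)
  for (t in 2:8) expect_identical(frames(a)[t, , ], frames(a)[1, , ])

  b1 <- simulateContractionVideo(nFrames = 10, noiseSigma = 0.05, seed = 42)
  b2 <- simulateContractionVideo(nFrames = 10, noiseSigma = 0.05, seed = 42)
  expect_identical(frames(b1), frames(b2))
  b3 <- simulateContractionVideo(nFrames = 10, noiseSigma = 0.05, seed = 43)
  expect_false(identical(frames(b1), frames(b3)))
})

test_that("disc radius is exactly periodic", {
  fs <- simulateContractionVideo(
    nFrames = 20, amplitude = 0.2, period = 10, noiseSigma = 0
  )
  expect_identical(frames(fs)[1, , ], frames(fs)[11, , ])
  # half a period later the disc is back through zero phase offset by sign
  expect_false(identical(frames(fs)[1, , ], frames(fs)[4, , ]))
})

test_that("video pixel values stay in [0, 1] after noise clipping", {
  fs <- simulateContractionVideo(
    nFrames = 12, noiseSigma = 0.5, fg = 0.9, bg = 0.1, seed = 7
  )
  expect_gte(min(frames(fs)), 0)
  expect_lte(max(frames(fs)), 1)
})

test_that("video generator rejects invalid geometry", {
  expect_error(simulateContractionVideo(nFrames = 4), "at least 5")
  expect_error(simulateContractionVideo(amplitude = 1), "amplitude")
  expect_error(
    simulateContractionVideo(height = 32, width = 32, baseRadius = 40),
    "exceeds"
  )
  expect_error(simulateContractionVideo(baseRadius = -1), "positive")
})

test_that("expression generator bookkeeping: labels match the cluster design", {
  sce <- simulateExpression(nClusters = 3, cellsPerCluster = 50, nGenes = 120,
                            markersPerCluster = 5, seed = 11)
  lab <- SingleCellExperiment::colLabels(sce)
  expect_length(lab, 150)
  expect_identical(as.integer(table(lab)), rep(50L, 3))
  m <- SummarizedExperiment::assay(sce, "counts")
  expect_identical(dim(m), c(120L, 150L))
  expect_true(all(m@x >= 0 & m@x %% 1 == 0))
})

test_that("null effect: zero marker logFC leaves non-channel true means flat", {
  ch <- data.frame(ligand = "G0100", receptor = "G0101",
                   sender = 1, receiver = 2)
  sce <- simulateExpression(nClusters = 3, cellsPerCluster = 10, nGenes = 120,
                            markersPerCluster = 5, markerLogFC = 0,
                            lrChannels = ch, seed = 5)
  mu <- S4Vectors::metadata(sce)$truth$trueMeans
  flat <- setdiff(rownames(mu), c("G0100", "G0101"))
  expect_true(all(mu[flat, 1] == mu[flat, 2] & mu[flat, 2] == mu[flat, 3]))
  expect_true(mu["G0100", 1] > 0 && all(mu["G0100", 2:3] == 0))
  expect_true(mu["G0101", 2] > 0 && all(mu["G0101", c(1, 3)] == 0))
})

test_that("planted marker enrichment matches the generating fold change", {
  sce <- simulateExpression(nClusters = 3, cellsPerCluster = 200, nGenes = 300,
                            markersPerCluster = 5, markerLogFC = 1,
                            baselineMean = 5, seed = 21)
  truth <- S4Vectors::metadata(sce)$truth
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  lab <- SingleCellExperiment::colLabels(sce)
  for (i in seq_len(nrow(truth$markers))) {
    g <- truth$markers$gene[i]
    k <- truth$markers$cluster[i]
    ratio <- mean(m[g, lab == k]) / mean(m[g, lab != k])
    expect_gt(ratio, exp(1) * 0.75)
    expect_lt(ratio, exp(1) * 1.25)
  }
})

test_that("expression generator validates its parameters", {
  expect_error(simulateExpression(nClusters = 0), "nClusters")
  expect_error(simulateExpression(nGenes = 0), "nGenes")
  expect_error(
    simulateExpression(nGenes = 50, nClusters = 4, markersPerCluster = 20),
    "too many marker genes"
  )
  ch <- data.frame(ligand = "G0001", receptor = "G0050",
                   sender = 1, receiver = 2)
  expect_error(
    simulateExpression(nGenes = 100, markersPerCluster = 5, lrChannels = ch),
    "disjoint from marker genes"
  )
  ch2 <- data.frame(ligand = "G0090", receptor = "G0091",
                    sender = 9, receiver = 2)
  expect_error(simulateExpression(nGenes = 100, lrChannels = ch2),
               "1:nClusters")
})

test_that("pair database combines planted and decoy pairs without duplicates", {
  planted <- data.frame(ligand = c("L1", "L2", "L3"),
                        receptor = c("R1", "R2", "R3"))
  expect_identical(
    simulateLRDatabase(planted)[, 1:2],
    planted
  )
  pool <- paste0("S", 1:20)
  db <- simulateLRDatabase(planted, nDecoys = 7, decoyGenes = pool, seed = 3)
  expect_identical(nrow(db), 10L)
  expect_false(anyDuplicated(db[, c("ligand", "receptor")]) > 0)
  decoys <- db[db$annotation == "decoy", ]
  expect_length(intersect(unlist(decoys[, 1:2]), unlist(planted)), 0)
  # deterministic under seed
  expect_identical(db, simulateLRDatabase(planted, 7, pool, seed = 3))

  expect_error(simulateLRDatabase(rbind(planted, planted[1, ])), "duplicate")
  expect_error(simulateLRDatabase(planted, 2, decoyGenes = c("L1", "x")),
               "disjoint")
})
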