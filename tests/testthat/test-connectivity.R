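smallProfile <- function(seed = 1) {
  set.seed(seed)
  cnt <- matrix(rpois(40 * 30, 2), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), paste0("c", 1:30)))
  labels <- factor(rep(c("A", "B", "C"), each = 10))
  sce <- makeSCE(cnt, labels)
  list(sce = logNormalize(sce), labels = labels)
}

test_that("cluster profile equals the per-cluster loop oracle", {
  fix <- smallProfile()
  prof <- buildClusterProfile(fix$sce)
  nm <- as.matrix(SummarizedExperiment::assay(fix$sce, "logcounts"))
  orc <- oracleProfile(nm, fix$labels)
  expect_equal(profileMeans(prof), orc$means, tolerance = 1e-12)
  expect_equal(profileDetection(prof), orc$detection, tolerance = 1e-12)
  expect_identical(unname(profileCells(prof)), rep(10L, 3))

  # single cluster: means are the row means
  one <- buildClusterProfile(nm, labels = factor(rep("all", 30)))
  expect_equal(profileMeans(one)[, 1], rowMeans(nm), tolerance = 1e-12)

  # an all-zero gene has mean 0 and detection 0
  cnt0 <- rbind(matrix(2, 3, 6), zero = 0)
  rownames(cnt0) <- c("a", "b", "c", "zero")
  colnames(cnt0) <- paste0("c", 1:6)
  p0 <- buildClusterProfile(logNormalize(cnt0), factor(rep(c("x", "y"), 3)))
  expect_identical(unname(profileMeans(p0)["zero", ]), c(0, 0))
  expect_identical(unname(profileDetection(p0)["zero", ]), c(0, 0))

  expect_error(buildClusterProfile(nm, labels = factor("A")), "exactly the cells")
})

test_that("presence calls follow the dual-threshold policy", {
  fix <- smallProfile()
  prof <- buildClusterProfile(fix$sce)

  vac <- callPresence(prof, minDetection = 0, minMean = 0)
  expect_true(all(presence(vac)[profileDetection(prof) > 0]))

  calls <- callPresence(prof, 0.1, 0.25)
  expect_identical(
    presence(calls),
    profileDetection(prof) >= 0.1 & profileMeans(prof) >= 0.25
  )
  expect_identical(unname(presencePolicy(calls)), c(0.1, 0.25))

  # raising a threshold never adds a call
  stricter <- callPresence(prof, 0.1, 0.8)
  expect_true(all(presence(calls) | !presence(stricter)))

  expect_error(callPresence(prof, minDetection = 2), "0, 1")
})

test_that("planted ligands are present in their sender cluster only", {
  ch <- data.frame(ligand = c("G0150", "G0152"), receptor = c("G0151", "G0153"),
                   sender = c(1, 3), receiver = 2)
  sce <- simulateExpression(nClusters = 3, cellsPerCluster = 60, nGenes = 200,
                            markersPerCluster = 5, markerLogFC = 1.5,
                            nbDispersion = 0, lrChannels = ch, seed = 50)
  sce <- logNormalize(filterCells(filterGenes(sce), minGenes = 40))
  calls <- callPresence(buildClusterProfile(sce))
  expect_identical(unname(presence(calls)["G0150", ]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(presence(calls)["G0151", ]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(presence(calls)["G0152", ]), c(FALSE, FALSE, TRUE))
})

test_that("interaction counts match exhaustive enumeration", {
  genes <- paste0("g", 1:12)
  cls <- c("A", "B", "C")
  for (seed in 1:5) {
    set.seed(seed)
    cm <- matrix(runif(36) > 0.5, 12, 3, dimnames = list(genes, cls))
    calls <- new("PresenceCalls", calls = cm, minDetection = 0, minMean = 0)
    db <- unique(data.frame(
      ligand = sample(genes, 8, replace = TRUE),
      receptor = sample(genes, 8, replace = TRUE)
    ))
    imap <- countInteractions(calls, db)
    expect_identical(interactionCounts(imap), oracleCounts(cm, db, cls, cls))
    # count/list consistency
    for (s in cls) {
      for (r in cls) {
        expect_identical(
          interactionCounts(imap)[s, r],
          nrow(contributingPairs(imap)[[paste0(s, "->", r)]])
        )
      }
    }
    # superset monotonicity
    sub <- db[seq_len(nrow(db) %/% 2), ]
    expect_true(all(interactionCounts(countInteractions(calls, sub)) <=
                      interactionCounts(imap)))
  }
})

test_that("empty databases, missing genes and orientation are handled", {
  cm <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
               dimnames = list(c("l1", "r1"), c("A", "B")))
  calls <- new("PresenceCalls", calls = cm, minDetection = 0, minMean = 0)

  empty <- countInteractions(calls, data.frame(ligand = character(),
                                               receptor = character()))
  expect_true(all(interactionCounts(empty) == 0))

  db <- data.frame(ligand = c("l1", "ghost"), receptor = c("r1", "r1"))
  imap <- countInteractions(calls, db)
  expect_identical(nrow(skippedPairs(imap)), 1L)
  expect_identical(skippedPairs(imap)$ligand, "ghost")
  expect_identical(interactionCounts(imap)["A", "B"], 1L)
  expect_identical(sum(interactionCounts(imap)), 1L)
  expect_equal(unname(senderMeans(imap)), c(0.5, 0))

  # swapping sender/receiver sets AND ligand/receptor roles transposes counts
  set.seed(9)
  cm2 <- matrix(runif(20) > 0.4, 10, 2,
                dimnames = list(paste0("g", 1:10), c("A", "B")))
  calls2 <- new("PresenceCalls", calls = cm2, minDetection = 0, minMean = 0)
  db2 <- data.frame(ligand = paste0("g", 1:5), receptor = paste0("g", 6:10))
  fwd <- countInteractions(calls2, db2)
  swapped <- data.frame(ligand = db2$receptor, receptor = db2$ligand)
  rev <- countInteractions(calls2, swapped)
  expect_identical(interactionCounts(rev), t(interactionCounts(fwd)))

  expect_error(countInteractions(calls, db, senders = "Z"), "cluster ids")
  expect_error(countInteractions(calls, rbind(db, db[1, ])), "duplicate")
})

test_that("pairing scores are mean products, ranked with lexicographic ties", {
  means <- matrix(c(2, 0, 1, 1, 0, 3), nrow = 3,
                  dimnames = list(c("l1", "l2", "r1"), c("A", "B")))
  prof <- new("ClusterProfile", means = means,
              detection = (means > 0) * 1, nCells = c(A = 5L, B = 5L))
  db <- data.frame(ligand = c("l1", "l2"), receptor = c("r1", "r1"))
  tbl <- scorePairings(prof, db)
  expect_identical(nrow(tbl), 8L)
  # zero mean on either side annihilates the score
  expect_true(all(tbl$score[tbl$ligand == "l2" & tbl$sender == "A"] == 0))
  top <- tbl[1, ]
  expect_identical(top$ligand, "l1")
  expect_identical(top$sender, "A")
  expect_identical(top$receiver, "B")
  expect_equal(top$score, 2 * 3)
  expect_true(all(diff(tbl$score) <= 0))
  # scores tied at 0 are ordered lexicographically
  zeros <- tbl[tbl$score == 0, ]
  key <- do.call(order, zeros[, c("ligand", "receptor", "sender", "receiver")])
  expect_identical(key, seq_len(nrow(zeros)))

  expect_identical(nrow(topPairings(tbl, 3)), 3L)
  expect_identical(topPairings(tbl, 100), tbl)
})

test_that("interaction heatmaps round-trip through CSV", {
  dir <- withr::local_tempdir()
  cm <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
               dimnames = list(c("l1", "r1"), c("A", "B")))
  calls <- new("PresenceCalls", calls = cm, minDetection = 0, minMean = 0)
  db <- data.frame(ligand = "l1", receptor = "r1")
  imap <- countInteractions(calls, db)
  meta <- renderInteractionHeatmap(imap, file.path(dir, "im"))
  expect_true(file.exists(file.path(dir, "im.png")))
  back <- as.matrix(utils::read.csv(file.path(dir, "im_counts.csv"),
                                    row.names = 1))
  expect_identical(unname(back), unname(interactionCounts(imap)))
  expect_false(meta$degenerate_scale)

  # a 1x1 zero map is flagged as degenerate
  z <- countInteractions(calls, data.frame(ligand = "l1", receptor = "l1"),
                         senders = "B", receivers = "B")
  mz <- renderInteractionHeatmap(z, file.path(dir, "zero"))
  expect_true(mz$degenerate_scale)
})
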