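test_that("grayscale conversion uses the luminance weights", {
  g <- array(0.37, dim = c(2, 3, 3, 3))
  expect_equal(frames(toGrayscale(g)), array(0.37, dim = c(2, 3, 3)))

  red <- array(0, dim = c(1, 1, 1, 3))
  red[1, 1, 1, 1] <- 1
  expect_equal(frames(toGrayscale(red))[1, 1, 1], 0.299)

  set.seed(8)
  a <- array(runif(2 * 4 * 5 * 3), dim = c(2, 4, 5, 3))
  expect_equal(frames(toGrayscale(a)), oracleGray(a), tolerance = 1e-15)

  expect_error(toGrayscale(array(0, dim = c(2, 3, 3, 2))), "color stack")
})

test_that("change heat matches the brute-force oracle bit-exactly", {
  for (seed in 1:5) {
    f <- randStack(10, 8, 8, seed)
    hm <- computeHeatMap(FrameStack(f), lag = 4)
    expect_identical(heat(hm), oracleHeat(f, 4))
    expect_identical(nPairs(hm), 6L)
    hd <- computeHeatMap(FrameStack(f), lag = 3, method = "disjoint")
    expect_identical(heat(hd), oracleHeat(f, 3, "disjoint"))
    expect_identical(nPairs(hd), 3L)
  }
})

test_that("change heat edge cases behave as hand-enumerated", {
  # constant stack: zero heat
  hm <- computeHeatMap(FrameStack(array(0.4, dim = c(6, 3, 3))))
  expect_true(all(heat(hm) == 0))

  # T = 5, lag = 4: exactly the pair (frame 1, frame 5)
  f <- randStack(5, 4, 4, 99)
  hm <- computeHeatMap(FrameStack(f), lag = 4)
  expect_identical(nPairs(hm), 1L)
  expect_identical(heat(hm), abs(f[5, , ] - f[1, , ]))

  # alternating pixel: lag 4 compares equal phases, lag 3 opposite phases
  f <- array(0, dim = c(8, 2, 2))
  f[, 1, 1] <- rep(c(0, 1), 4)
  expect_identical(heat(computeHeatMap(FrameStack(f), lag = 4))[1, 1], 0)
  expect_identical(heat(computeHeatMap(FrameStack(f), lag = 3))[1, 1], 1)

  expect_error(
    computeHeatMap(FrameStack(array(0, dim = c(4, 2, 2))), lag = 4),
    "lag 4.*got 4"
  )
})

test_that("heat is bounded, order-insensitive and spatially equivariant", {
  f <- randStack(12, 6, 7, 31)
  hm <- heat(computeHeatMap(FrameStack(f)))
  expect_true(all(hm >= 0 & hm <= 1))

  rev <- f[12:1, , , drop = FALSE]
  expect_identical(heat(computeHeatMap(FrameStack(rev))), hm)

  py <- sample(6)
  px <- sample(7)
  perm <- f[, py, px, drop = FALSE]
  hp <- heat(computeHeatMap(FrameStack(perm)))
  expect_identical(hp, hm[py, px])
  expect_identical(
    contractionScore(computeHeatMap(FrameStack(perm)))$score,
    contractionScore(computeHeatMap(FrameStack(f)))$score
  )
})

test_that("heat and score are homogeneous in intensity", {
  f <- randStack(10, 8, 8, 77)
  h1 <- computeHeatMap(FrameStack(f))
  h2 <- computeHeatMap(FrameStack(0.5 * f))
  expect_equal(heat(h2), 0.5 * heat(h1), tolerance = 1e-14)
  expect_equal(contractionScore(h2)$score, 0.5 * contractionScore(h1)$score,
               tolerance = 1e-14)
})

test_that("contraction score reduces heat over the frame or a mask", {
  z <- new("HeatMap", heat = matrix(0, 4, 4), lag = 4L, nPairs = 2L,
           method = "sliding", sourceId = "z")
  expect_identical(contractionScore(z)$score, 0)

  cst <- new("HeatMap", heat = matrix(0.2, 4, 4), lag = 4L, nPairs = 2L,
             method = "sliding", sourceId = "c")
  mask <- matrix(c(rep(TRUE, 5), rep(FALSE, 11)), 4, 4)
  sc <- contractionScore(cst, mask = mask, group = "MR")
  expect_equal(sc$score, 0.2)
  expect_identical(sc$mask_area, 5L)
  expect_identical(sc$group, "MR")
  expect_error(contractionScore(cst, mask = matrix(FALSE, 4, 4)), "no pixels")
  expect_error(contractionScore(cst, mask = matrix(TRUE, 2, 2)), "dimensions")
})

test_that("contraction score increases with contraction amplitude", {
  scores <- vapply(c(0.05, 0.1, 0.2), function(a) {
    fs <- simulateContractionVideo(nFrames = 30, amplitude = a,
                                   noiseSigma = 0, seed = 1)
    contractionScore(computeHeatMap(fs))$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("heat image rendering scales linearly and round-trips", {
  dir <- withr::local_tempdir()

  z <- new("HeatMap", heat = matrix(0, 5, 5), lag = 4L, nPairs = 1L,
           method = "sliding", sourceId = "zero")
  p0 <- file.path(dir, "zero.png")
  renderHeatImage(z, p0)
  expect_true(all(png::readPNG(p0) == 0))

  h <- matrix(0, 5, 5)
  h[2, 3] <- 0.37
  hm <- new("HeatMap", heat = h, lag = 4L, nPairs = 1L,
            method = "sliding", sourceId = "one")
  p1 <- file.path(dir, "one.png")
  meta <- renderHeatImage(hm, p1)
  img <- png::readPNG(p1)
  expect_equal(img[2, 3], 1)
  expect_equal(meta$scale_max, 0.37)

  f <- randStack(8, 10, 10, 5)
  hm <- computeHeatMap(FrameStack(f))
  p2 <- file.path(dir, "rand.png")
  renderHeatImage(hm, p2)
  back <- readHeatImage(p2)
  expect_lt(max(abs(back - heat(hm))), max(heat(hm)) / 255 + 1e-12)
})

test_that("group comparison reproduces the closed-form ANOVA", {
  # null: identical groups
  s <- data.frame(score = rep(c(1, 2, 3), 2),
                  group = rep(c("a", "b"), each = 3))
  res <- compareGroups(s)
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p, 1)
  expect_identical(res$anova$stars, "")

  # separated means
  s2 <- data.frame(
    score = c(0, 1e-3, -1e-3, 1, 1 + 1e-3, 1 - 1e-3),
    group = rep(c("lo", "hi"), each = 3)
  )
  r2 <- compareGroups(s2)
  expect_lt(r2$anova$p, 0.001)
  expect_identical(r2$anova$stars, "***")

  # random groups against the between/within mean-square ratio
  set.seed(12)
  for (i in 1:3) {
    y <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    r <- compareGroups(data.frame(score = y, group = g))
    expect_equal(r$anova$F, oracleAnovaF(y, g), tolerance = 1e-10)
    expect_identical(r$groups$n, rep(10L, 3))
  }

  expect_error(
    compareGroups(data.frame(score = c(1, 2, 3), group = c("a", "a", "b"))),
    "'b'"
  )
  expect_error(compareGroups(data.frame(score = 1:3, group = "a")),
               "two groups")
})
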