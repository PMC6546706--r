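#' Convert a color frame stack to grayscale luminance
#'
#' Collapses a `T x H x W x 3` RGB stack to luminance with the Rec. 601
#' weights `0.299 R + 0.587 G + 0.114 B`. A stack that is already grayscale
#' (a `T x H x W` array or a `FrameStack`) passes through unchanged.
#'
#' @param x a `T x H x W x 3` numeric array with values in `[0, 1]`, a
#'   `T x H x W` grayscale array, or a [FrameStack-class].
#' @param frameInterval,sourceId metadata forwarded to the returned stack.
#'
#' @return A [FrameStack-class] of luminance frames.
#' @export
toGrayscale <- function(x, frameInterval = NA_real_, sourceId = "unknown") {
  if (methods::is(x, "FrameStack")) {
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    return(FrameStack(x, frameInterval, sourceId))
  }
  if (length(d) != 4L || d[4L] != 3L) {
    stop("expected a T x H x W x 3 color stack or a T x H x W grayscale stack")
  }
  g <- 0.299 * x[, , , 1L] + 0.587 * x[, , , 2L] + 0.114 * x[, , , 3L]
  dim(g) <- d[1:3]
  FrameStack(g, frameInterval, sourceId)
}

#' Compute the per-pixel change heat of a video
#'
#' The core motion statistic: grayscale differences between frames a fixed
#' lag apart are taken over the whole video and their absolute values are
#' averaged per pixel, giving the "change heat" of each image region. With
#' the default sliding pairing every valid pair `(t, t + lag)` contributes,
#' so for `T` frames `T - lag` pairs are averaged:
#'
#' `heat(x, y) = 1/(T - lag) * sum_t |I(t + lag, x, y) - I(t, x, y)|`
#'
#' The disjoint pairing (`method = "disjoint"`) instead steps `t` by `lag`,
#' using non-overlapping pairs only. Squared differencing is available for
#' sensitivity studies (`squared = TRUE`); the default magnitude of change
#' is the absolute difference.
#'
#' @param stack a [FrameStack-class] (or anything [toGrayscale()] accepts).
#' @param lag frame lag (default 4).
#' @param method `"sliding"` (all pairs `(t, t + lag)`) or `"disjoint"`
#'   (pairs stepping by `lag`).
#' @param squared use squared instead of absolute differences.
#'
#' @return A [HeatMap-class]; heat values lie in `[0, 1]` for intensity
#'   input in `[0, 1]` (absolute differencing).
#' @examples
#' fs <- simulateContractionVideo(nFrames = 20, amplitude = 0.2, noiseSigma = 0)
#' hm <- computeHeatMap(fs, lag = 4)
#' hm
#' @export
computeHeatMap <- function(stack, lag = 4L,
                           method = c("sliding", "disjoint"),
                           squared = FALSE) {
  stack <- toGrayscale(stack)
  method <- match.arg(method)
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be a positive integer")
  f <- stack@frames
  nT <- dim(f)[1L]
  if (nT <= lag) {
    stop(sprintf(
      "need more than %d frames for lag %d differencing, got %d",
      lag, lag, nT
    ))
  }
  starts <- switch(method,
    sliding = seq_len(nT - lag),
    disjoint = seq.int(1L, nT - lag, by = lag)
  )
  d <- f[starts + lag, , , drop = FALSE] - f[starts, , , drop = FALSE]
  d <- if (squared) d * d else abs(d)
  h <- colMeans(d, dims = 1L)
  new("HeatMap",
    heat = h, lag = lag, nPairs = length(starts),
    method = method, sourceId = stack@sourceId
  )
}

#' Reduce a heat map to a scalar contraction score
#'
#' The contraction intensity of one organoid video: the spatial mean of its
#' change heat, over the whole frame by default or over a boolean region of
#' interest. A perfectly static video scores exactly 0; intensities in
#' `[0, 1]` bound the score by 1.
#'
#' @param hm a [HeatMap-class].
#' @param mask optional logical `H x W` matrix selecting the region to
#'   average over; must match the heat map shape and select at least one
#'   pixel.
#' @param group optional group label carried into the returned row (e.g.
#'   culture condition).
#'
#' @return A one-row data frame with columns `source_id`, `group`, `lag`,
#'   `n_pairs`, `mask_area`, `score`.
#' @export
contractionScore <- function(hm, mask = NULL, group = NA_character_) {
  stopifnot(methods::is(hm, "HeatMap"))
  h <- hm@heat
  if (is.null(mask)) {
    area <- length(h)
    score <- mean(h)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(h))) {
      stop("'mask' must be a logical matrix with the heat map's dimensions")
    }
    if (!any(mask)) stop("'mask' selects no pixels")
    area <- sum(mask)
    score <- mean(h[mask])
  }
  data.frame(
    source_id = hm@sourceId, group = as.character(group),
    lag = hm@lag, n_pairs = hm@nPairs,
    mask_area = area, score = score,
    stringsAsFactors = FALSE
  )
}

#' Render a heat map as an 8-bit grayscale PNG
#'
#' Linearly rescales heat from `[0, max(heat)]` to `[0, 255]` (brighter =
#' stronger local contraction; an all-zero map renders all black) and writes
#' the scaling bounds to a JSON sidecar next to the image so the rendering
#' is invertible up to 8-bit quantization.
#'
#' @param hm a [HeatMap-class].
#' @param path output PNG path; the sidecar is written to `<path>.json`.
#'
#' @return Invisibly, the sidecar metadata list.
#' @export
renderHeatImage <- function(hm, path) {
  stopifnot(methods::is(hm, "HeatMap"))
  hmax <- max(hm@heat)
  img <- if (hmax > 0) hm@heat / hmax else hm@heat
  ok <- tryCatch(
    {
      png::writePNG(img, target = path)
      TRUE
    },
    error = function(e) {
      stop("cannot write heat image to '", path, "': ", conditionMessage(e))
    }
  )
  meta <- list(
    source_id = hm@sourceId, lag = hm@lag, n_pairs = hm@nPairs,
    scale_min = 0, scale_max = hmax, bits = 8L
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(meta)
}

#' Read a rendered heat image back to heat values
#'
#' Inverse of [renderHeatImage()] up to 8-bit quantization, using the JSON
#' sidecar's scaling bounds.
#'
#' @param path PNG path written by [renderHeatImage()].
#' @return A numeric matrix of reconstructed heat values.
#' @export
readHeatImage <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- png::readPNG(path)
  img * meta$scale_max
}

#' Compare contraction scores across groups by one-way ANOVA
#'
#' Given per-video contraction scores labeled by experimental group (e.g.
#' co-culture vs. monoculture organoids), computes the one-way ANOVA F test
#' across groups together with per-group summaries, and annotates the p-value
#' with conventional significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001).
#'
#' @param scores data frame of per-video scores, e.g. rows from
#'   [contractionScore()].
#' @param scoreCol,groupCol column names of the score and the group label.
#'
#' @return A list with `anova` (one-row data frame: `df_between`,
#'   `df_within`, `F`, `p`, `stars`) and `groups` (per-group `n`, `mean`,
#'   `sd`).
#' @export
compareGroups <- function(scores, scoreCol = "score", groupCol = "group") {
  scores <- as.data.frame(scores)
  if (!all(c(scoreCol, groupCol) %in% names(scores))) {
    stop("score/group columns not found in 'scores'")
  }
  y <- scores[[scoreCol]]
  g <- factor(scores[[groupCol]])
  if (nlevels(g) < 2L) stop("at least two groups are required")
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop(sprintf(
      "group '%s' has fewer than 2 observations",
      names(sizes)[which(sizes < 2L)[1L]]
    ))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  fval <- fit[["F value"]][1L]
  pval <- fit[["Pr(>F)"]][1L]
  stars <- if (pval < 0.001) "***" else if (pval < 0.01) "**" else
    if (pval < 0.05) "*" else ""
  groups <- data.frame(
    group = levels(g),
    n = as.integer(sizes),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, stats::sd)),
    stringsAsFactors = FALSE
  )
  list(
    anova = data.frame(
      df_between = fit$Df[1L], df_within = fit$Df[2L],
      F = fval, p = pval, stars = stars, stringsAsFactors = FALSE
    ),
    groups = groups
  )
}
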