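# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive per-pixel loops so they stay independent of the
# package's vectorised/compiled implementations.

.cache <- new.env(parent = emptyenv())

# classifier trained once per test run on a generated training set
testModel <- function() {
  if (is.null(.cache$model)) {
    ts <- generateTrainingSet(slideSpec(seed = 101L), nImages = 6L)
    .cache$model <- trainPixelClassifier(
      images = lapply(ts, `[[`, "image"),
      labelMasks = lapply(ts, `[[`, "labelMask"))
  }
  .cache$model
}

smallSpec <- function(nTriads, seed, noiseSd = 8,
                      distractors = integer(0)) {
  slideSpec(nTriads = nTriads, distractors = distractors,
            dims = c(1120L, 1680L), noiseSd = noiseSd, seed = seed)
}

# brute-force contact fraction: per-pixel loops over the 8-neighbourhood
bfContactFraction <- function(object, neighborMask) {
  h <- nrow(object); w <- ncol(object)
  boundary <- 0L; contact <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!object[i, j]) next
    isB <- FALSE; hasN <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w) { isB <- TRUE; next }
      if (!object[ii, jj]) isB <- TRUE
      if (neighborMask[ii, jj]) hasN <- TRUE
    }
    if (isB) {
      boundary <- boundary + 1L
      if (hasN) contact <- contact + 1L
    }
  }
  list(boundary = boundary, contact = contact,
       fraction = if (boundary > 0) contact / boundary else NaN)
}

# brute-force boundary-pixel count of a mask
bfBoundaryCount <- function(mask) {
  bfContactFraction(mask, mask & FALSE)$boundary
}

# brute-force 8-connected components by flood fill
bfComponents8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nextLab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nextLab
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# brute-force even-odd (crossing number) point-in-polygon
bfPointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# run morphometry straight from a ground-truth label map (no classifier),
# returning the marker-bearing TMEM object set
cascadeFromLabels <- function(labelMap, calibration = calibrationParams(),
                              params = morphometryParams()) {
  obj <- formObjects(labelMap, calibration, params)
  obj <- filterObjects(obj, params)
  tset <- reclassifyCascade(obj, params)
  makeTmemObjects(tset, params)
}

# score a slide straight from its ground-truth label map
scoreFromLabels <- function(labelMap, calibration = calibrationParams(),
                            params = morphometryParams(),
                            scoring = scoringParams()) {
  tset <- cascadeFromLabels(labelMap, calibration, params)
  tiles <- iterTiles(dim(labelMap), fullRoi(dim(labelMap)), calibration)
  counts <- countPerTile(tset, tiles, scoring)
  rankAndScore(counts, scoring)$score
}

# blank canvas of stroma
stromaCanvas <- function(h, w) matrix(labelScheme()[["STROMA"]], h, w)
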