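# minimal TMEMObjectSet carrying only markers, for tile-count tests
fakeMarkerSet <- function(x, y, cal = calibrationParams()) {
  n <- length(x)
  methods::new("TMEMObjectSet",
    vessels = data.frame(id = seq_len(n), areaUm2 = rep(1, n), x = x, y = y),
    macrophages = data.frame(id = integer(0), size = character(0),
                             areaUm2 = numeric(0), x = numeric(0),
                             y = numeric(0)),
    vesselLab = matrix(0L, 1, 1), macLab = matrix(0L, 1, 1),
    markers = data.frame(parentId = seq_len(n), x = x, y = y,
                         markerAreaUm2 = rep(1, n)),
    markerMasks = list(), interfaceUm = 0, calibration = cal)
}

test_that("markers land in exactly one tile via the parent centroid", {
  cal <- calibrationParams()                    # tiles 840 x 1120 px
  dims <- c(2240L, 2520L)
  tiles <- iterTiles(dims, fullRoi(dims), cal)
  expect_equal(nrow(tiles), 6L)

  # three markers in one tile
  s <- fakeMarkerSet(x = c(100.5, 200.5, 300.5), y = c(100.5, 150.5, 900.5))
  ct <- countPerTile(s, tiles)
  expect_equal(sum(ct$count), 3L)
  expect_equal(ct$count[ct$row == 0 & ct$col == 0], 3L)

  # centroid exactly on a shared tile edge: assigned to exactly one tile
  # (the half-open convention puts x = 840 in tile column 1)
  edge <- fakeMarkerSet(x = 840, y = 1120)
  ce <- countPerTile(edge, tiles)
  expect_equal(sum(ce$count), 1L)
  expect_equal(ce$count[ce$row == 1 & ce$col == 1], 1L)

  # conservation: totals match marker counts on random layouts, and each
  # marker's tile agrees with a brute-force half-open containment check
  set.seed(99)
  for (rep in 1:10) {
    n <- sample.int(20, 1)
    x <- runif(n, 0, 2519); y <- runif(n, 0, 2239)
    ct <- countPerTile(fakeMarkerSet(x, y), tiles)
    expect_equal(sum(ct$count), n)
    bf <- integer(nrow(ct))
    for (i in seq_len(n)) {
      hit <- which(x[i] >= ct$x0 & x[i] < ct$x0 + ct$wPx &
                   y[i] >= ct$y0 & y[i] < ct$y0 + ct$hPx)
      expect_length(hit, 1L)
      bf[hit] <- bf[hit] + 1L
    }
    expect_equal(ct$count, bf)
  }
})

test_that("tiles below the ROI-overlap floor are excluded from counting", {
  cal <- calibrationParams()
  dims <- c(1120L, 1680L)
  roi <- matrix(FALSE, dims[1], dims[2])
  roi[, 1:1000] <- TRUE                         # second tile ~19% covered
  tiles <- iterTiles(dims, roi, cal)
  expect_equal(nrow(tiles), 2L)
  s <- fakeMarkerSet(x = c(100, 900), y = c(100, 100))
  ct <- countPerTile(s, tiles, scoringParams(minTileRoiOverlap = 0.5))
  expect_equal(nrow(ct), 1L)                    # low-overlap tile dropped
  expect_equal(sum(ct$count), 1L)               # its marker is not counted
  ctAll <- countPerTile(s, tiles, scoringParams(minTileRoiOverlap = 0))
  expect_equal(sum(ctAll$count), 2L)
})

test_that("ranking sums the top-K with the stated deterministic tie-break", {
  mkTiles <- function(counts) data.frame(
    index = seq_along(counts) - 1L, row = 0L, col = seq_along(counts) - 1L,
    x0 = 0L, y0 = 0L, wPx = 10L, hPx = 10L, roiOverlap = 1,
    count = counts)
  # 15 tiles of one -> top-10 scores 10
  r <- rankAndScore(mkTiles(rep(1L, 15)))
  expect_equal(r$score, 10)
  # all zero -> 0
  expect_equal(rankAndScore(mkTiles(rep(0L, 12)))$score, 0)
  # counts 7,5,5,3 with top_k = 2 -> 12, second place to the lower index
  r2 <- rankAndScore(mkTiles(c(7L, 5L, 5L, 3L)), scoringParams(topK = 2))
  expect_equal(r2$score, 12)
  expect_equal(r2$topTiles, c(1L, 2L))
  expect_equal(r2$tiles$rank, c(1L, 2L, NA, NA))
  # fewer tiles than top_k -> all tiles summed
  expect_equal(rankAndScore(mkTiles(c(3L, 4L)))$score, 7)
})

test_that("the three quantification metrics behave on planted and empty slides", {
  lab <- stromaCanvas(400, 400)
  lab <- TMEMscore:::.paintStructure(lab, "triad", 200, 200, 0.357)
  tset <- cascadeFromLabels(lab)
  m <- alternativeMetrics(tset)
  expect_equal(unname(m[c("taVessels", "taMacrophages")]), c(1, 1))
  expect_gt(m[["interfaceUm"]], 0)

  empty <- cascadeFromLabels(stromaCanvas(300, 300))
  expect_equal(unname(alternativeMetrics(empty)), c(0, 0, 0))

  # interface length equals the brute-force adjacency count x mpp
  bf <- bfContactFraction(tset@macLab > 0, tset@vesselLab > 0)
  expect_equal(m[["interfaceUm"]], bf$contact * 0.357)
})

test_that("risk categories follow the published cutoffs", {
  expect_equal(classifyRisk(0), "low")
  expect_equal(classifyRisk(6), "low")
  expect_equal(classifyRisk(7), "intermediate")
  expect_equal(classifyRisk(10), "intermediate")
  expect_equal(classifyRisk(23), "intermediate")
  expect_equal(classifyRisk(24), "high")
  expect_equal(classifyRisk(100), "high")
  expect_error(classifyRisk(-1), "non-negative")
  expect_error(riskParams(10, 5))
})

test_that("planting one more triad in a counted tile raises the score by one", {
  lab <- stromaCanvas(1120, 840)                # exactly one HPF tile
  lab <- TMEMscore:::.paintStructure(lab, "triad", 250, 250, 0.357)
  lab <- TMEMscore:::.paintStructure(lab, "triad", 700, 500, 0.357)
  s2 <- scoreFromLabels(lab)
  lab3 <- TMEMscore:::.paintStructure(lab, "triad", 250, 600, 0.357)
  s3 <- scoreFromLabels(lab3)
  expect_equal(s2, 2)
  expect_equal(s3, 3)
})

test_that("scoreSlide is exact on clean slides and fully deterministic", {
  model <- testModel()
  # no TMEM, no distractors -> 0
  g0 <- generateSlide(smallSpec(0, seed = 71, noiseSd = 0))
  s0 <- scoreSlide(g0$image, model = model)
  expect_equal(tmemScore(s0), 0)
  expect_equal(riskCategory(s0), "low")

  # 7 well-separated triads, full-image ROI -> exactly 7
  g7 <- generateSlide(smallSpec(7, seed = 72, noiseSd = 0))
  s7 <- scoreSlide(g7$image, model = model)
  expect_equal(tmemScore(s7), 7)
  expect_equal(tmemScore(s7), expectedCount(g7$truth))
  # score never exceeds the total TMEM objects in the ROI
  expect_lte(tmemScore(s7), nrow(tmemMarkers(attr(s7, "tmemSet"))))

  # identical rerun -> identical SlideScore
  s7b <- scoreSlide(g7$image, model = model)
  expect_equal(tmemScore(s7b), tmemScore(s7))
  expect_identical(tileCounts(s7b), tileCounts(s7))
  expect_identical(tmemMetrics(s7b), tmemMetrics(s7))

  # restricting the ROI away from every triad zeroes the score
  roi <- matrix(FALSE, 1120, 1680)
  roi[1:50, 1:50] <- TRUE
  sr <- scoreSlide(g7$image, model = model, roi = roi)
  expect_equal(tmemScore(sr), 0)
})
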