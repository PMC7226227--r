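test_that("image I/O round-trips 8-bit RGB and rejects non-RGB input", {
  td <- withr::local_tempdir()
  white <- array(255L, dim = c(100, 100, 3))
  p <- file.path(td, "white.png")
  writeSlideImage(white, p)
  expect_identical(readSlideImage(p), white)

  spec <- smallSpec(1, seed = 5)
  img <- generateSlide(spec)$image
  for (ext in c("png", "tif")) {
    f <- file.path(td, paste0("slide.", ext))
    writeSlideImage(img, f)
    expect_identical(readSlideImage(f), img)
  }

  gray <- file.path(td, "gray.png")
  png::writePNG(matrix(0.5, 10, 10), gray)
  expect_error(readSlideImage(gray), "3 channels")
  expect_error(readSlideImage(file.path(td, "nope.png")), "not found")
})

test_that("polygon ROIs rasterize by pixel-centre inclusion", {
  dims <- c(40L, 60L)
  # full-frame rectangle -> all ones
  rect <- cbind(x = c(0, 60, 60, 0), y = c(0, 0, 40, 40))
  full <- loadRoi(list(rect), dims)
  expect_true(all(full))

  # generic triangles vs the brute-force crossing-number oracle
  set.seed(33)
  for (rep in 1:5) {
    tri <- cbind(x = runif(3, 1, 59) + 0.123, y = runif(3, 1, 39) + 0.234)
    mask <- tryCatch(loadRoi(list(tri), dims), error = function(e) NULL)
    oracle <- matrix(FALSE, dims[1], dims[2])
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      oracle[i, j] <- bfPointInPolygon(j - 0.5, i - 0.5, tri)
    if (is.null(mask)) {          # degenerate triangle missed every centre
      expect_equal(sum(oracle), 0)
    } else {
      expect_identical(unclass(mask)[, ], oracle,
                       label = paste("triangle", rep))
    }
  }

  expect_error(loadRoi(list(), dims), "empty")

  # GeoJSON file path
  td <- withr::local_tempdir()
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(
      list(list(5, 5), list(20, 5), list(20, 15), list(5, 15), list(5, 5)))))))
  f <- file.path(td, "roi.geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  m <- loadRoi(f, dims)
  expect_equal(sum(m), 15 * 10)  # 15 x 10 pixel centres inside
})

test_that("mask-image ROIs must match the image grid and be nonempty", {
  td <- withr::local_tempdir()
  f <- file.path(td, "m.png")
  png::writePNG(matrix(c(0, 1), 10, 8), f)
  expect_error(loadRoi(f, c(12L, 8L)), "does not match")
  m <- loadRoi(f, c(10L, 8L))
  expect_equal(sum(m), 40)
  png::writePNG(matrix(0, 10, 8), f)
  expect_error(loadRoi(f, c(10L, 8L)), "empty")
})

test_that("HPF tile grid has the right pixel geometry and tiles the ROI bbox", {
  cal <- calibrationParams(mpp = 0.357, tileWidthUm = 300, tileHeightUm = 400)
  dims <- c(1200L, 1600L)
  tiles <- iterTiles(dims, fullRoi(dims), cal)
  # 300 um / 0.357 um/px ~ 840 px, 400 um -> 1120 px
  expect_true(all(tiles$wPx == 840L))
  expect_true(all(tiles$hPx == 1120L))
  expect_equal(nrow(tiles), ceiling(1600 / 840) * ceiling(1200 / 1120))
  # row-major order and non-overlap
  expect_equal(tiles$index, seq_len(nrow(tiles)) - 1L)
  expect_equal(order(tiles$row, tiles$col), seq_len(nrow(tiles)))
  corners <- paste(tiles$x0, tiles$y0)
  expect_equal(anyDuplicated(corners), 0L)
  # grid covers the ROI bounding box
  expect_true(max(tiles$x0 + tiles$wPx) >= dims[2])
  expect_true(max(tiles$y0 + tiles$hPx) >= dims[1])

  # ROI covering exactly one tile -> one tile with overlap 1
  roi <- matrix(FALSE, 1200, 1600)
  roi[1:1120, 1:840] <- TRUE
  t1 <- iterTiles(dims, roi, cal)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$roiOverlap, 1)

  # determinism
  expect_identical(tiles, iterTiles(dims, fullRoi(dims), cal))

  # degenerate calibration
  expect_error(iterTiles(dims, fullRoi(dims),
                         calibrationParams(mpp = 500, tileWidthUm = 300)),
               "smaller than 1 px")
})

test_that("score reports write JSON, CSV and an overlay PNG", {
  td <- withr::local_tempdir()
  spec <- smallSpec(2, seed = 9, noiseSd = 0)
  g <- generateSlide(spec)
  s <- scoreSlide(g$image, model = testModel())
  files <- writeScoreReport(s, file.path(td, "case1"), image = g$image,
                            tmemSet = attr(s, "tmemSet"))
  expect_true(all(file.exists(files)))
  rep <- jsonlite::read_json(file.path(td, "case1.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$score, tmemScore(s))
  expect_equal(rep$risk, riskCategory(s))
  expect_equal(rep$metrics$ta_vessels, unname(tmemMetrics(s)["taVessels"]))
  csv <- utils::read.csv(file.path(td, "case1_tiles.csv"))
  expect_equal(nrow(csv), nrow(tileCounts(s)))
  expect_equal(sum(csv$count), sum(tileCounts(s)$count))
})
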