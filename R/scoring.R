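# Scoring: assign TMEM objects to HPF tiles, rank tiles, sum the top-K,
# compute the alternative quantification metrics, and assign risk.

#' Count TMEM objects per tile
#'
#' Each TMEM marker is assigned to exactly one tile: the tile containing
#' its parent TA-vessel centroid (half-open pixel convention, so a centroid
#' on a shared edge lands in exactly one tile). Tiles whose ROI overlap is
#' below the minimum are excluded from the ranking, and markers falling in
#' excluded tiles (or outside the grid) are not counted.
#'
#' @param tmemSet a [TMEMObjectSet-class] with markers.
#' @param tiles tile table from [iterTiles()].
#' @param scoring a [ScoringParams-class].
#' @return the eligible subset of `tiles` with a `count` column.
#' @export
countPerTile <- function(tmemSet, tiles, scoring = scoringParams()) {
  eligible <- tiles[tiles$roiOverlap >= scoring@minTileRoiOverlap, ,
                    drop = FALSE]
  eligible$count <- rep(0L, nrow(eligible))
  mk <- tmemSet@markers
  if (nrow(mk) > 0 && nrow(eligible) > 0) {
    tw <- tiles$wPx[1]; th <- tiles$hPx[1]
    x0 <- min(tiles$x0); y0 <- min(tiles$y0)
    col <- floor((mk$x - x0) / tw)
    row <- floor((mk$y - y0) / th)
    key <- paste(row, col)
    tab <- table(key[row >= 0 & col >= 0])
    ekey <- paste(eligible$row, eligible$col)
    hit <- match(ekey, names(tab))
    eligible$count <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  eligible
}

#' Rank tiles and compute the TMEM score
#'
#' Sorts tiles by TMEM count descending, ties broken by row-major tile
#' index, and sums the counts of the first `topK` tiles (all tiles when
#' fewer exist). The sum over the top 10 ranked high-power fields is the
#' final TMEM (MetaSite) score.
#'
#' @param tileCounts tile table with a `count` column from
#'   [countPerTile()].
#' @param scoring a [ScoringParams-class].
#' @return list with `score`, `topTiles` (row indices into `tileCounts`,
#'   in rank order), and `tiles` (the input with a `rank` column).
#' @export
rankAndScore <- function(tileCounts, scoring = scoringParams()) {
  ord <- order(-tileCounts$count, tileCounts$index)
  k <- min(scoring@topK, nrow(tileCounts))
  top <- ord[seq_len(k)]
  tileCounts$rank <- rep(NA_integer_, nrow(tileCounts))
  tileCounts$rank[top] <- seq_len(k)
  list(score = sum(tileCounts$count[top]),
       topTiles = as.integer(top),
       tiles = tileCounts)
}

#' The three TMEM quantification metrics
#'
#' Returns the number of TMEM-associated vessels (the primary score basis:
#' ~1 per underlying TMEM doorway, the scale pathologists use), the number
#' of TMEM-associated macrophages, and the total interface length (um)
#' between TA-macrophages and TA-vessels. The three are strongly
#' rank-correlated across slides since they share the doorway-count driver.
#'
#' @param tmemSet a [TMEMObjectSet-class].
#' @return named numeric vector (taVessels, taMacrophages, interfaceUm).
#' @export
alternativeMetrics <- function(tmemSet) {
  c(taVessels = nrow(tmemSet@vessels),
    taMacrophages = nrow(tmemSet@macrophages),
    interfaceUm = tmemSet@interfaceUm)
}

#' Assign the risk category
#'
#' Low if score <= lowCutoff (default 6), high if score > highCutoff
#' (default 23), intermediate otherwise. The boundary convention is a
#' configuration-visible choice and is echoed in reports.
#'
#' @param score TMEM score (>= 0).
#' @param risk a [RiskParams-class].
#' @return "low", "intermediate", or "high".
#' @export
classifyRisk <- function(score, risk = riskParams()) {
  if (score < 0) stop("score must be non-negative")
  if (score <= risk@lowCutoff) "low"
  else if (score > risk@highCutoff) "high"
  else "intermediate"
}

#' Score a slide end to end
#'
#' Runs the full pipeline: stain feature extraction, per-pixel
#' classification, ROI masking (pixels outside the ROI are treated as
#' stroma/background), object formation and size filtering, the TMEM
#' reclassification cascade, marker dilation, HPF tiling, per-tile
#' counting, ranking, the three quantification metrics, and the risk
#' category. Fully deterministic: the same inputs always give the
#' identical result.
#'
#' @param image RGB raster (integer H x W x 3) or a path readable by
#'   [readSlideImage()].
#' @param model a [ClassifierModel-class] or a model JSON path; `NULL`
#'   falls back to `config@classifierPath`.
#' @param roi logical ROI mask, a path readable by [loadRoi()], or `NULL`
#'   for the full image.
#' @param config a [TMEMConfig-class].
#' @return a [SlideScore-class]. The TMEM object set is attached as
#'   attribute `tmemSet` for overlay rendering.
#' @export
scoreSlide <- function(image, model = NULL, roi = NULL,
                       config = defaultConfig()) {
  t0 <- proc.time()[["elapsed"]]
  log1 <- function(stage) {
    if (config@verbosity > 0L)
      message(sprintf("[tmem] %-12s %7.2fs", stage,
                      proc.time()[["elapsed"]] - t0))
  }
  if (is.character(image)) image <- readSlideImage(image)
  dims <- dim(image)[1:2]
  if (is.null(model)) {
    if (!nzchar(config@classifierPath))
      stop("no classifier model supplied and none configured")
    model <- readClassifier(config@classifierPath)
  } else if (is.character(model)) {
    model <- readClassifier(model)
  }
  if (is.null(roi)) roi <- fullRoi(dims)
  else if (is.character(roi)) roi <- loadRoi(roi, dims)
  if (!any(roi)) stop("ROI is empty")

  fs <- extractFeatures(image, config@stains, config@medianRadius)
  log1("features")
  lab <- classifyPixels(fs, model)
  lab[!roi] <- labelScheme()[["STROMA"]]
  log1("classify")
  obj <- formObjects(lab, config@calibration, config@morphometry)
  obj <- filterObjects(obj, config@morphometry)
  log1("objects")
  tset <- reclassifyCascade(obj, config@morphometry)
  tset <- makeTmemObjects(tset, config@morphometry)
  log1("cascade")
  tiles <- iterTiles(dims, roi, config@calibration)
  counts <- countPerTile(tset, tiles, config@scoring)
  rk <- rankAndScore(counts, config@scoring)
  metrics <- alternativeMetrics(tset)
  risk <- classifyRisk(rk$score, config@risk)
  log1("score")
  out <- methods::new("SlideScore",
    score = rk$score, risk = risk, metrics = metrics,
    tiles = rk$tiles, topTiles = rk$topTiles,
    params = .paramsEcho(config))
  attr(out, "tmemSet") <- tset
  out
}

#' @noRd
.paramsEcho <- function(config) {
  list(
    calibration = list(
      microns_per_pixel = config@calibration@mpp,
      tile_width_um = config@calibration@tileWidthUm,
      tile_height_um = config@calibration@tileHeightUm),
    morphometry = .morphometryAsList(config@morphometry),
    scoring = list(top_k = config@scoring@topK,
                   min_tile_roi_overlap = config@scoring@minTileRoiOverlap),
    risk = list(low_cutoff = config@risk@lowCutoff,
                high_cutoff = config@risk@highCutoff,
                convention = "low: score <= low_cutoff; high: score > high_cutoff"),
    median_radius = config@medianRadius,
    config_hash = configHash(config))
}
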