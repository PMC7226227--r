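# Image, ROI and report I/O. Rasters are integer H x W x 3 arrays with
# 8-bit values 0..255; all coordinates exposed to the user are 0-based.

#' Read an RGB slide image
#'
#' Reads an 8-bit, 3-channel PNG or TIFF image. Grayscale or alpha-carrying
#' images are rejected: the pipeline is defined on RGB triple-IHC images.
#'
#' @param path path to a .png, .tif or .tiff file.
#' @return integer H x W x 3 array with values in 0..255.
#' @export
readSlideImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)"))
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected 3 channels (RGB), got ",
         if (length(dim(img)) == 2) 1 else dim(img)[3])
  out <- array(as.integer(round(img * 255)), dim = dim(img))
  out
}

#' Write an RGB slide image
#'
#' @param raster integer H x W x 3 array, values 0..255.
#' @param path output path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
writeSlideImage <- function(raster, path) {
  if (length(dim(raster)) != 3 || dim(raster)[3] != 3)
    stop("raster must be H x W x 3")
  img <- array(pmin(pmax(raster, 0L), 255L) / 255, dim = dim(raster))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

# rasterize closed polygons (0-based pixel coordinates) by pixel-centre
# inclusion; `polys` is a list of n x 2 matrices with columns x, y
#' @noRd
.rasterizePolygons <- function(polys, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (p in polys) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop("each polygon needs an n x 2 matrix of >= 3 vertices")
    # simple-polygon check: consecutive duplicated vertices only
    rs <- max(1L, floor(min(p[, 2]))):min(dims[1], ceiling(max(p[, 2])) + 1L)
    cs <- max(1L, floor(min(p[, 1]))):min(dims[2], ceiling(max(p[, 1])) + 1L)
    if (!length(rs) || !length(cs)) next
    centres <- cbind(x = rep(cs - 0.5, each = length(rs)),
                     y = rep(rs - 0.5, times = length(cs)))
    inside <- mgcv::in.out(rbind(p, p[1, , drop = FALSE]), centres)
    sub <- matrix(inside, nrow = length(rs))
    mask[rs, cs] <- mask[rs, cs] | sub
  }
  mask
}

#' Load a region-of-interest mask
#'
#' Reads either an 8-bit mask image (non-zero = inside ROI; must match the
#' image grid) or a GeoJSON file of polygons in 0-based pixel coordinates,
#' rasterized by pixel-centre inclusion with half-open pixels. The ROI
#' restricts all scoring to the pathologist-delimited invasive tumor.
#'
#' @param path path to a mask PNG/TIFF or a .json/.geojson polygon file;
#'   alternatively a list of n x 2 polygon matrices (columns x, y).
#' @param dims integer c(height, width) of the slide image.
#' @return logical H x W matrix with attribute `provenance` ("drawn").
#' @export
loadRoi <- function(path, dims) {
  if (is.list(path) && !is.character(path)) {
    if (!length(path)) stop("empty polygon list")
    mask <- .rasterizePolygons(path, dims)
  } else {
    if (!file.exists(path)) stop("ROI file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("json", "geojson")) {
      polys <- .readGeoJsonPolygons(path)
      if (!length(polys)) stop("empty polygon list")
      mask <- .rasterizePolygons(polys, dims)
    } else {
      img <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported ROI format: .", ext))
      if (length(dim(img)) == 3) img <- img[, , 1]
      if (!all(dim(img) == dims))
        stop("ROI mask shape ", paste(dim(img), collapse = "x"),
             " does not match image shape ", paste(dims, collapse = "x"))
      mask <- img > 0
    }
  }
  if (!any(mask)) stop("ROI is empty")
  attr(mask, "provenance") <- "drawn"
  mask
}

#' Full-image ROI
#'
#' @param dims integer c(height, width).
#' @return logical all-TRUE mask with provenance "full-image".
#' @export
fullRoi <- function(dims) {
  mask <- matrix(TRUE, dims[1], dims[2])
  attr(mask, "provenance") <- "full-image"
  mask
}

#' @noRd
.readGeoJsonPolygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]  # outer ring only
      polys[[length(polys) + 1L]] <-
        do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    } else if (identical(geom$type, "MultiPolygon")) {
      for (pg in geom$coordinates)
        polys[[length(polys) + 1L]] <-
          do.call(rbind, lapply(pg[[1]], function(v) c(v[[1]], v[[2]])))
    }
  }
  lapply(polys, function(p) {
    colnames(p) <- c("x", "y")
    # drop a closing vertex identical to the first
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), ]
    p
  })
}

#' Enumerate high-power-field tiles over the ROI
#'
#' Lays a non-overlapping grid of HPF-sized tiles (physical size converted
#' to pixels, rounded) anchored at the ROI bounding-box origin, emitted in
#' row-major order. Each tile carries the fraction of its nominal area
#' covered by the ROI (tiles reaching past the image edge lose that area
#' too).
#'
#' @param dims integer c(height, width) of the image in px.
#' @param roi logical ROI mask (see [loadRoi()]/[fullRoi()]).
#' @param calibration a [CalibrationParams-class].
#' @return data.frame with columns index (0-based, row-major), row, col,
#'   x0, y0 (0-based px origin), wPx, hPx, roiOverlap.
#' @export
iterTiles <- function(dims, roi, calibration) {
  if (calibration@tileWidthUm / calibration@mpp < 1 ||
      calibration@tileHeightUm / calibration@mpp < 1)
    stop("tile smaller than 1 px at this calibration")
  tw <- as.integer(round(calibration@tileWidthUm / calibration@mpp))
  th <- as.integer(round(calibration@tileHeightUm / calibration@mpp))
  if (!any(roi)) stop("ROI is empty")
  rw <- range(which(rowSums(roi) > 0)); cw <- range(which(colSums(roi) > 0))
  r0 <- rw[1]; c0 <- cw[1]
  nr <- ceiling((rw[2] - r0 + 1) / th)
  nc <- ceiling((cw[2] - c0 + 1) / tw)
  grid <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  grid <- grid[, c("row", "col")]
  grid$index <- seq_len(nrow(grid)) - 1L
  grid$x0 <- (c0 - 1L) + grid$col * tw
  grid$y0 <- (r0 - 1L) + grid$row * th
  grid$wPx <- tw
  grid$hPx <- th
  grid$roiOverlap <- vapply(seq_len(nrow(grid)), function(i) {
    rs <- (grid$y0[i] + 1L):min(grid$y0[i] + th, dims[1])
    cs <- (grid$x0[i] + 1L):min(grid$x0[i] + tw, dims[2])
    if (grid$y0[i] + 1L > dims[1] || grid$x0[i] + 1L > dims[2]) return(0)
    sum(roi[rs, cs]) / (tw * th)
  }, numeric(1))
  rownames(grid) <- NULL
  grid[, c("index", "row", "col", "x0", "y0", "wPx", "hPx", "roiOverlap")]
}

#' Write score report artifacts
#'
#' Writes `<prefix>.json` (score, risk, metrics, ranked tiles, effective
#' parameters and config hash), `<prefix>_tiles.csv` (one row per eligible
#' tile), and, when `image` is supplied, `<prefix>_overlay.png` with the
#' top-ranked tiles outlined and TMEM markers drawn.
#'
#' @param slideScore a [SlideScore-class].
#' @param prefix output path prefix.
#' @param image optional RGB raster for the overlay.
#' @param tmemSet optional [TMEMObjectSet-class] whose marker outlines are
#'   drawn on the overlay.
#' @return character vector of the files written, invisibly.
#' @export
writeScoreReport <- function(slideScore, prefix, image = NULL,
                             tmemSet = NULL) {
  files <- character(0)
  tiles <- slideScore@tiles
  jsonPath <- paste0(prefix, ".json")
  rep <- list(
    score = slideScore@score,
    risk = slideScore@risk,
    metrics = list(ta_vessels = unname(slideScore@metrics[["taVessels"]]),
                   ta_macs = unname(slideScore@metrics[["taMacrophages"]]),
                   interface_um = unname(slideScore@metrics[["interfaceUm"]])),
    tiles = tiles,
    params_echo = slideScore@params)
  jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, jsonPath)
  csvPath <- paste0(prefix, "_tiles.csv")
  utils::write.csv(tiles, csvPath, row.names = FALSE)
  files <- c(files, csvPath)
  if (!is.null(image)) {
    ovPath <- paste0(prefix, "_overlay.png")
    writeSlideImage(.drawOverlay(image, slideScore, tmemSet), ovPath)
    files <- c(files, ovPath)
  }
  invisible(files)
}

#' @noRd
.drawOverlay <- function(image, slideScore, tmemSet = NULL) {
  img <- image
  h <- dim(img)[1]; w <- dim(img)[2]
  tiles <- slideScore@tiles
  paintPx <- function(rs, cs, col) {
    rs <- rs[rs >= 1 & rs <= h]; cs <- cs[cs >= 1 & cs <= w]
    if (!length(rs) || !length(cs)) return()
    for (k in 1:3) img[rs, cs, k] <<- col[k]
  }
  for (i in slideScore@topTiles) {
    y <- tiles$y0[i] + 1L; x <- tiles$x0[i] + 1L
    y1 <- min(y + tiles$hPx[i] - 1L, h); x1 <- min(x + tiles$wPx[i] - 1L, w)
    col <- c(255L, 220L, 0L)                       # yellow tile frame
    paintPx(y:(min(y + 2L, y1)), x:x1, col)
    paintPx((max(y1 - 2L, y)):y1, x:x1, col)
    paintPx(y:y1, x:(min(x + 2L, x1)), col)
    paintPx(y:y1, (max(x1 - 2L, x)):x1, col)
  }
  if (!is.null(tmemSet)) {
    for (m in tmemSet@markerMasks) {
      b <- .boundaryMask(m$mask)
      idx <- which(b)
      if (!length(idx)) next
      rr <- (idx - 1L) %% nrow(b) + m$r0
      cc <- (idx - 1L) %/% nrow(b) + m$c0
      keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      for (k in 1:3)
        img[cbind(rr[keep], cc[keep], k)] <- c(20L, 20L, 140L)[k]
    }
  }
  img
}
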