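# Stain feature extraction: Beer-Lambert optical density, non-negative
# least-squares unmixing onto the stain color directions, and per-channel
# median filtering.

#' Convert 8-bit RGB to optical density
#'
#' Beer-Lambert transform `od = -log10((v + 1) / 256)` per channel: white
#' (no absorbance) maps to ~0, black to the maximum OD; lower intensity
#' means higher OD. Stains mix additively in this space.
#'
#' @param raster integer H x W x 3 RGB array (0..255), or an n x 3 matrix
#'   of pixel values.
#' @return numeric array/matrix of the same shape, values >= 0.
#' @export
rgbToOD <- function(raster) {
  v <- pmin(pmax(as.integer(raster), 0L), 255L)
  lut <- -log10((0:255 + 1) / 256)
  out <- lut[v + 1L]
  dim(out) <- dim(raster)
  dimnames(out) <- dimnames(raster)
  out
}

#' Build a stain matrix from reference colors
#'
#' Converts named 8-bit RGB reference colors (one per stain) to unit OD
#' direction vectors.
#'
#' @param reference named list or 3 x k matrix of RGB reference colors
#'   (0..255); names/colnames are the stain names.
#' @return a [StainMatrix-class].
#' @export
stainMatrix <- function(reference) {
  if (is.list(reference))
    reference <- vapply(reference, as.numeric, numeric(3))
  reference <- as.matrix(reference)
  if (nrow(reference) != 3) stop("reference colors must be RGB triples")
  od <- apply(reference, 2, function(col) {
    v <- rgbToOD(matrix(as.integer(round(col)), 1, 3))
    v <- as.numeric(v)
    n <- sqrt(sum(v^2))
    if (n < 1e-8)
      stop("reference color ", paste(col, collapse = ","),
           " is white: no OD direction")
    v / n
  })
  storage.mode(reference) <- "integer"
  methods::new("StainMatrix", od = od, reference = reference)
}

#' Default stain matrix
#'
#' Stain directions fitted to the synthetic renderer's reference colors:
#' vessel (Vector Blue stand-in), macrophage (DAB stand-in), tumor (Fast
#' Red stand-in, from the darkly stained tone), and the light-green
#' counterstain. Override with measured chromogen colors for real slides.
#'
#' @return a [StainMatrix-class] with 4 stains.
#' @export
defaultStainMatrix <- function() {
  pal <- defaultPalette()
  stainMatrix(list(
    vessel = pal["VESSEL", ],
    macrophage = pal["MACROPHAGE", ],
    tumor = pal["TUMOR_DARK", ],
    counterstain = pal["STROMA", ]))
}

# Exact non-negative least squares of each OD pixel onto the stain
# directions, by enumeration of supports of size <= 3. With four stains in
# 3-D OD space the unconstrained LS solution is non-unique, so plain
# "solve then clip" is ill-defined; the NNLS optimum always admits a
# support of size <= rank, so enumerating full-rank supports is exact.
# Ties (equal residual) resolve to the smaller, earlier support, which
# keeps single-stain pixels on their own channel.
#' @noRd
.unmixNNLS <- function(odm, M) {
  k <- ncol(M)
  n <- nrow(odm)
  subsets <- list()
  for (size in 1:min(3, k))
    subsets <- c(subsets, utils::combn(k, size, simplify = FALSE))
  bestResid <- rep(Inf, n)
  bestSubset <- rep(0L, n)
  cache <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    S <- subsets[[si]]
    MS <- M[, S, drop = FALSE]
    g <- crossprod(MS)
    if (abs(det(g)) < 1e-12) next
    CS <- odm %*% MS %*% solve(g)              # n x |S| LS coefficients
    feas <- CS[, 1] >= -1e-12
    if (ncol(CS) > 1)
      for (j in 2:ncol(CS)) feas <- feas & (CS[, j] >= -1e-12)
    fitted <- CS %*% t(MS)
    resid <- rowSums((odm - fitted)^2)
    resid[!feas] <- Inf
    better <- resid < bestResid - 1e-12
    bestResid[better] <- resid[better]
    bestSubset[better] <- si
    cache[[si]] <- CS
  }
  conc <- matrix(0, n, k)
  for (si in unique(bestSubset[bestSubset > 0L])) {
    sel <- bestSubset == si
    conc[sel, subsets[[si]]] <- pmax(cache[[si]][sel, , drop = FALSE], 0)
  }
  conc
}

#' Extract stain feature channels
#'
#' Converts the RGB image to optical density, unmixes each pixel onto the
#' stain directions by least squares with non-negative concentrations
#' (exact NNLS for overcomplete matrices; for a full-column-rank matrix the
#' plain LS solution with negatives clipped to 0), and median-filters each
#' channel to aid signal separation. The result is the per-stain contrast
#' stack fed to the pixel classifier.
#'
#' @param raster integer H x W x 3 RGB array (0..255).
#' @param stains a [StainMatrix-class].
#' @param medianRadius median filter radius in px (0 = no filtering;
#'   default 1, i.e. a 3 x 3 kernel).
#' @return a [FeatureStack-class].
#' @export
extractFeatures <- function(raster, stains, medianRadius = 1L) {
  stopifnot(length(dim(raster)) == 3, dim(raster)[3] == 3)
  medianRadius <- as.integer(medianRadius)
  if (medianRadius < 0L) stop("medianRadius must be >= 0")
  M <- stains@od
  h <- dim(raster)[1]; w <- dim(raster)[2]
  # 8-bit RGB triples repeat heavily: unmix each distinct color once
  v <- pmin(pmax(as.integer(raster), 0L), 255L)
  key <- v[1:(h * w)] + 256L * v[(h * w + 1):(2 * h * w)] +
    65536L * v[(2 * h * w + 1):(3 * h * w)]
  uk <- unique(key)
  urgb <- cbind(uk %% 256L, (uk %/% 256L) %% 256L, uk %/% 65536L)
  odm <- rgbToOD(urgb)
  concU <- if (ncol(M) <= 3 && qr(M)$rank == ncol(M))
    pmax(odm %*% M %*% solve(crossprod(M)), 0)
  else
    .unmixNNLS(odm, M)
  conc <- concU[match(key, uk), , drop = FALSE]
  stack <- array(conc, dim = c(h, w, ncol(M)),
                 dimnames = list(NULL, NULL, colnames(M)))
  if (medianRadius > 0L)
    for (j in seq_len(ncol(M)))
      stack[, , j] <- .medianFilterSq(stack[, , j], medianRadius)
  methods::new("FeatureStack", data = stack,
               channels = colnames(M), medianRadius = medianRadius)
}
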