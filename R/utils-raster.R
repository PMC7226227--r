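# Low-level raster helpers shared by the morphometry and synthetic modules.
# All matrices are H x W, row-major semantics, 1-based internally; public
# pixel coordinates are 0-based with half-open tiles (pixel (r, c) covers
# [c, c+1) x [r, r+1), centre (c + 0.5, r + 0.5)).

# offsets of the 8-neighbourhood
.N8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1,  0,  1, -1, 1, -1, 0, 1))

#' @noRd
.asMat <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  x
}

# result[r, c] = m[r + dr, c + dc], out-of-image filled with `fill`
#' @noRd
.shiftMat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  if (length(rs) && length(cs)) out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# TRUE where at least one 8-neighbour is TRUE in `mask`
#' @noRd
.neighbor8Any <- function(mask) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(.N8)))
    out <- out | .shiftMat(mask, .N8[i, 1L], .N8[i, 2L], FALSE)
  out
}

# TRUE where all 8 neighbours are TRUE (out-of-image counts as FALSE)
#' @noRd
.neighbor8All <- function(mask) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(.N8)))
    out <- out & .shiftMat(mask, .N8[i, 1L], .N8[i, 2L], FALSE)
  out
}

# boundary pixel = object pixel with >= 1 non-object 8-neighbour or on the
# image edge. Implemented as mask minus its 3x3 erosion; the mask is padded
# with one background pixel so image edges count as outside (EBImage's
# erode pads with foreground).
#' @noRd
.boundaryMask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  er <- .asMat(EBImage::erode(p, EBImage::makeBrush(3L, "box"))) > 0
  mask & !er[2:(h + 1L), 2:(w + 1L)]
}

# fast adjacency for disjoint masks: TRUE on or next to `mask` (3x3
# dilation); equals .neighbor8Any wherever the querying pixels are not
# themselves in `mask`
#' @noRd
.dilate8 <- function(mask) {
  .asMat(EBImage::dilate(mask, EBImage::makeBrush(3L, "box"))) > 0
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find pass.
#' @noRd
.label8 <- function(mask) {
  lab <- .asMat(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1L) return(lab)
  pairs <- NULL
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    sh <- .shiftMat(lab, off[1L], off[2L], 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(lab[sel], sh[sel])))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1L]); b <- find(pairs[i, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# per-label pixel counts for an integer label matrix
#' @noRd
.labelCounts <- function(lab, nbins = max(lab, 0L)) {
  if (nbins == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins)
}

# per-label centroids in 0-based pixel-centre coordinates; returns a matrix
# with columns x, y (NA for empty labels)
#' @noRd
.labelCentroids <- function(lab, nbins = max(lab, 0L)) {
  out <- matrix(NA_real_, nbins, 2, dimnames = list(NULL, c("x", "y")))
  if (nbins == 0L) return(out)
  idx <- which(lab > 0L)
  if (!length(idx)) return(out)
  l <- lab[idx]
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  n <- tabulate(l, nbins)
  sx <- vapply(split(cc, factor(l, levels = seq_len(nbins))), sum, numeric(1))
  sy <- vapply(split(rr, factor(l, levels = seq_len(nbins))), sum, numeric(1))
  out[, "x"] <- sx / n - 0.5
  out[, "y"] <- sy / n - 0.5
  out
}

# per-label boundary pixel counts and neighbour-contact pixel counts.
# Objects of one 8-connected labelling are never mutually 8-adjacent, so the
# boundary of the union mask splits cleanly by label.
#' @noRd
.labelContact <- function(lab, neighborMask, boundary = NULL) {
  n <- max(lab, 0L)
  if (n == 0L) return(list(boundary = integer(0), contact = integer(0)))
  b <- if (is.null(boundary)) .boundaryMask(lab > 0L) else boundary
  adj <- b & .dilate8(neighborMask)  # lab classes are disjoint from the
                                     # neighbour class, so dilation equals
                                     # strict 8-neighbour adjacency here
  list(boundary = tabulate(lab[b], n), contact = tabulate(lab[adj], n))
}

# shift with replicated edges (for neighbourhood filters)
#' @noRd
.shiftMatEdge <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w)]
}

# exact square median filter of radius r with replicated edges (compiled)
#' @noRd
.medianFilterSq <- function(m, r) {
  if (r <= 0L) return(m)
  .medianFilterSqCpp(m, as.integer(r))
}

# paint a filled disk of radius r px (pixel-centre inclusion) with `code`
#' @noRd
.paintDisk <- function(lab, cy, cx, r, code) {
  h <- nrow(lab); w <- ncol(lab)
  rs <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(rs) || !length(cs)) return(lab)
  d2 <- outer((rs - cy)^2, (cs - cx)^2, "+")
  sub <- lab[rs, cs, drop = FALSE]
  sub[d2 <= r^2] <- code
  lab[rs, cs] <- sub
  lab
}

# paint a half annulus r0 < d <= r1 on the side rows <= cy (upper) or > cy
#' @noRd
.paintHalfAnnulus <- function(lab, cy, cx, r0, r1, code, upper = TRUE) {
  h <- nrow(lab); w <- ncol(lab)
  rs <- max(1L, floor(cy - r1)):min(h, ceiling(cy + r1))
  cs <- max(1L, floor(cx - r1)):min(w, ceiling(cx + r1))
  d2 <- outer((rs - cy)^2, (cs - cx)^2, "+")
  half <- if (upper) outer(rs <= cy, rep(TRUE, length(cs))) else
    outer(rs > cy, rep(TRUE, length(cs)))
  sel <- d2 > r0^2 & d2 <= r1^2 & half
  sub <- lab[rs, cs, drop = FALSE]
  sub[sel] <- code
  lab[rs, cs] <- sub
  lab
}
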