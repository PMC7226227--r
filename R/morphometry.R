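# Morphometry: object formation from the label map, size filtering, and
# the reclassification cascade that ends in TMEM-associated vessels and
# macrophages plus the dilated TMEM marker objects.
#
# Discrete conventions (fixed throughout): 8-connectivity for components
# and adjacency; a boundary pixel is an object pixel with at least one
# non-object 8-neighbour (image edges count as outside); contact fraction
# is the share of boundary pixels 8-adjacent to the neighbour class, so the
# unit of perimeter cancels.

#' Form smoothed tissue objects from a label map
#'
#' Merges the two tumor classes, smooths each merged class mask by
#' morphological closing with a disk (the dilate-then-erode boundary
#' smoothing), resolves overlaps created by closing with the fixed priority
#' VESSEL > MACROPHAGE > TUMOR > STROMA (rarest structures win), and labels
#' 8-connected components per class with area, perimeter and centroid.
#'
#' @param labelMap integer H x W matrix with the codes of [labelScheme()].
#' @param calibration a [CalibrationParams-class].
#' @param params a [MorphometryParams-class] (provides the smoothing
#'   radius, in um).
#' @return a [TissueObjects-class].
#' @export
formObjects <- function(labelMap, calibration,
                        params = morphometryParams()) {
  scheme <- labelScheme()
  mpp <- calibration@mpp
  masks <- list(
    TUMOR = labelMap == scheme[["TUMOR_DARK"]] |
            labelMap == scheme[["TUMOR_LIGHT"]],
    STROMA = labelMap == scheme[["STROMA"]],
    VESSEL = labelMap == scheme[["VESSEL"]],
    MACROPHAGE = labelMap == scheme[["MACROPHAGE"]])
  rpx <- as.integer(round(params@smoothingRadiusUm / mpp))
  if (rpx > 0L) {
    brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
    masks <- lapply(masks, function(m)
      .asMat(EBImage::closing(m, brush)) > 0)
  }
  # priority resolution: assign lowest priority first, overwrite upward
  final <- matrix(1L, nrow(labelMap), ncol(labelMap))  # 1 = STROMA fallback
  order <- c("STROMA", "TUMOR", "MACROPHAGE", "VESSEL")
  codes <- c(STROMA = 1L, TUMOR = 2L, MACROPHAGE = 3L, VESSEL = 4L)
  for (cls in order) final[masks[[cls]]] <- codes[[cls]]
  labels <- list()
  statsRows <- list()
  for (cls in .mergedClasses()) {
    lab <- .label8(final == codes[[cls]])
    labels[[cls]] <- lab
    n <- max(lab, 0L)
    if (n > 0L) {
      npx <- .labelCounts(lab, n)
      per <- tabulate(lab[.boundaryMask(lab > 0L)], n)
      cen <- .labelCentroids(lab, n)
      statsRows[[cls]] <- data.frame(
        class = cls, id = seq_len(n), nPx = npx,
        areaUm2 = npx * mpp^2, perimeterPx = per, perimeterUm = per * mpp,
        x = cen[, "x"], y = cen[, "y"])
    }
  }
  stats <- if (length(statsRows)) do.call(rbind, statsRows) else
    data.frame(class = character(0), id = integer(0), nPx = integer(0),
               areaUm2 = numeric(0), perimeterPx = integer(0),
               perimeterUm = numeric(0), x = numeric(0), y = numeric(0))
  rownames(stats) <- NULL
  methods::new("TissueObjects", labels = labels, stats = stats,
               calibration = calibration)
}

#' Remove implausibly sized objects
#'
#' Removes vessel and macrophage objects larger than the aggregate limit
#' (area > 800 um^2 by default) and small fragments: tumor < 10 um^2,
#' stroma < 400 um^2, macrophages < 5 um^2, vessels < 5 um^2. Inequalities
#' are strict exactly as printed, so an object of exactly 800 um^2 or
#' exactly 5 um^2 is kept. Removed objects are blanked from the label
#' matrices; remaining ids are unchanged.
#'
#' @param objects a [TissueObjects-class].
#' @param params a [MorphometryParams-class].
#' @return the filtered [TissueObjects-class].
#' @export
filterObjects <- function(objects, params = morphometryParams()) {
  st <- objects@stats
  drop <- rep(FALSE, nrow(st))
  a <- st$areaUm2
  drop[st$class %in% c("VESSEL", "MACROPHAGE") &
         a > params@maxVesselOrMacAggregateUm2] <- TRUE
  drop[st$class == "TUMOR" & a < params@minTumorFragmentUm2] <- TRUE
  drop[st$class == "STROMA" & a < params@minStromaUm2] <- TRUE
  drop[st$class == "MACROPHAGE" & a < params@minMacrophageUm2] <- TRUE
  drop[st$class == "VESSEL" & a < params@minVesselUm2] <- TRUE
  labels <- objects@labels
  for (cls in unique(st$class[drop])) {
    ids <- st$id[drop & st$class == cls]
    lab <- labels[[cls]]
    lab[lab %in% ids] <- 0L
    labels[[cls]] <- lab
  }
  methods::new("TissueObjects", labels = labels,
               stats = st[!drop, , drop = FALSE],
               calibration = objects@calibration)
}

#' Perimeter-contact fraction of one object
#'
#' Fraction of the object's boundary pixels that are 8-adjacent to at least
#' one pixel of the neighbour-class mask. A boundary pixel is an object
#' pixel with at least one non-object 8-neighbour (or lying on the image
#' edge).
#'
#' @param object logical H x W mask of one object (nonempty).
#' @param neighborMask logical H x W mask of the neighbour class.
#' @return contact fraction in [0, 1].
#' @export
contactFraction <- function(object, neighborMask) {
  if (!any(object)) stop("empty object")
  b <- .boundaryMask(object)
  sum(b & .neighbor8Any(neighborMask)) / sum(b)
}

#' Run the TMEM reclassification cascade
#'
#' Executes, in order, on the size-filtered objects: (a) vessels with >= 2%
#' macrophage perimeter contact become vessel-macrophage complexes; (b)
#' macrophages touching any such complex (contact > 0) become
#' macrophage-vessel complexes; (c) macrophage-vessel complexes >= 40 um^2
#' with >= 8% tumor and >= 20% vessel contact become large TMEM-associated
#' macrophages, those < 40 um^2 with >= 10% and >= 10% become small ones;
#' (d) vessel-macrophage complexes with >= 20% tumor contact and >= 20%
#' contact with TMEM-associated macrophages become TMEM-associated vessels;
#' (e) everything else is discarded. Vessel contact in (c) and tumor
#' contact throughout are measured against the union masks of all
#' post-filter vessels / tumor.
#'
#' @param objects a filtered [TissueObjects-class].
#' @param params a [MorphometryParams-class].
#' @return a [TMEMObjectSet-class] (markers empty until
#'   [makeTmemObjects()]).
#' @export
reclassifyCascade <- function(objects, params = morphometryParams()) {
  mpp <- objects@calibration@mpp
  st <- objects@stats
  vesselLab <- objects@labels$VESSEL
  macLab <- objects@labels$MACROPHAGE
  tumorMask <- objects@labels$TUMOR > 0L
  vesselMask <- vesselLab > 0L
  macMask <- macLab > 0L
  emptySet <- function() methods::new("TMEMObjectSet",
    vessels = data.frame(id = integer(0), areaUm2 = numeric(0),
                         x = numeric(0), y = numeric(0)),
    macrophages = data.frame(id = integer(0), size = character(0),
                             areaUm2 = numeric(0), x = numeric(0),
                             y = numeric(0)),
    vesselLab = matrix(0L, nrow(vesselLab), ncol(vesselLab)),
    macLab = matrix(0L, nrow(macLab), ncol(macLab)),
    markers = .emptyMarkers(), markerMasks = list(),
    interfaceUm = 0, calibration = objects@calibration)
  nV <- max(vesselLab, 0L); nM <- max(macLab, 0L)
  if (nV == 0L || nM == 0L) return(emptySet())
  bVessel <- .boundaryMask(vesselMask)
  bMac <- .boundaryMask(macMask)

  # (a) vessel-macrophage complexes
  cvMac <- .labelContact(vesselLab, macMask, bVessel)
  fracVMac <- ifelse(cvMac$boundary > 0, cvMac$contact / cvMac$boundary, 0)
  vmcIds <- which(fracVMac >= params@vesselMacContactMin)
  if (!length(vmcIds)) return(emptySet())
  vmcMask <- vesselLab > 0L & matrix(vesselLab %in% vmcIds,
                                     nrow(vesselLab), ncol(vesselLab))

  # (b) macrophage-vessel complexes: any contact with a VMC
  cmVmc <- .labelContact(macLab, vmcMask, bMac)
  mvcIds <- which(cmVmc$contact > 0L)
  if (!length(mvcIds)) return(emptySet())

  # (c) TMEM-associated macrophages, large/small by area
  cmTumor <- .labelContact(macLab, tumorMask, bMac)
  cmVessel <- .labelContact(macLab, vesselMask, bMac)
  fmTumor <- ifelse(cmTumor$boundary > 0, cmTumor$contact / cmTumor$boundary, 0)
  fmVessel <- ifelse(cmVessel$boundary > 0,
                     cmVessel$contact / cmVessel$boundary, 0)
  macArea <- .labelCounts(macLab, nM) * mpp^2
  large <- intersect(mvcIds, which(
    macArea >= params@largeMacThresholdUm2 &
      fmTumor >= params@largeMacTumorContactMin &
      fmVessel >= params@largeMacVesselContactMin))
  small <- intersect(mvcIds, which(
    macArea < params@largeMacThresholdUm2 &
      fmTumor >= params@smallMacTumorContactMin &
      fmVessel >= params@smallMacVesselContactMin))
  taMacIds <- c(large, small)
  if (!length(taMacIds)) return(emptySet())
  taMacMask <- macLab > 0L & matrix(macLab %in% taMacIds,
                                    nrow(macLab), ncol(macLab))

  # (d) TMEM-associated vessels
  cvTumor <- .labelContact(vesselLab, tumorMask, bVessel)
  cvTaMac <- .labelContact(vesselLab, taMacMask, bVessel)
  fvTumor <- ifelse(cvTumor$boundary > 0,
                    cvTumor$contact / cvTumor$boundary, 0)
  fvTaMac <- ifelse(cvTaMac$boundary > 0,
                    cvTaMac$contact / cvTaMac$boundary, 0)
  taVesselIds <- intersect(vmcIds, which(
    fvTumor >= params@taVesselTumorContactMin &
      fvTaMac >= params@taVesselMacContactMin))
  if (!length(taVesselIds)) return(emptySet())

  # (e) keep only TA objects
  taVesselLab <- vesselLab
  taVesselLab[!(vesselLab %in% taVesselIds)] <- 0L
  taMacLab <- macLab
  taMacLab[!(macLab %in% taMacIds)] <- 0L

  vSt <- st[st$class == "VESSEL" & st$id %in% taVesselIds, ]
  mSt <- st[st$class == "MACROPHAGE" & st$id %in% taMacIds, ]
  vessels <- data.frame(id = vSt$id, areaUm2 = vSt$areaUm2,
                        x = vSt$x, y = vSt$y)
  macs <- data.frame(id = mSt$id,
                     size = ifelse(mSt$id %in% large, "large", "small"),
                     areaUm2 = mSt$areaUm2, x = mSt$x, y = mSt$y)

  # total TA-macrophage / TA-vessel interface (boundary pixels x mpp)
  bTaMac <- bMac & (taMacLab > 0L)
  interfacePx <- sum(bTaMac & .dilate8(taVesselLab > 0L))

  methods::new("TMEMObjectSet",
               vessels = vessels[order(vessels$id), , drop = FALSE],
               macrophages = macs[order(macs$id), , drop = FALSE],
               vesselLab = taVesselLab, macLab = taMacLab,
               markers = .emptyMarkers(), markerMasks = list(),
               interfaceUm = interfacePx * mpp,
               calibration = objects@calibration)
}

#' @noRd
.emptyMarkers <- function() {
  data.frame(parentId = integer(0), x = numeric(0), y = numeric(0),
             markerAreaUm2 = numeric(0))
}

#' Create dilated TMEM marker objects
#'
#' Each TMEM-associated vessel is independently dilated by a disk of the
#' configured radius (50 um by default; 140 px at 0.357 um/px), emulating
#' the circles drawn in manual scoring. Each dilation is one TMEM marker
#' object carrying its parent vessel id and centroid; overlapping markers
#' remain distinct (one per TA-vessel) and a marker always covers at least
#' its parent vessel.
#'
#' @param tmemSet a [TMEMObjectSet-class] from [reclassifyCascade()].
#' @param params a [MorphometryParams-class] (dilation radius).
#' @return the [TMEMObjectSet-class] with markers filled in.
#' @export
makeTmemObjects <- function(tmemSet, params = morphometryParams()) {
  mpp <- tmemSet@calibration@mpp
  rpx <- round(params@tmemDilationUm / mpp)
  lab <- tmemSet@vesselLab
  h <- nrow(lab); w <- ncol(lab)
  markers <- list(); masks <- list()
  for (i in seq_len(nrow(tmemSet@vessels))) {
    id <- tmemSet@vessels$id[i]
    idx <- which(lab == id)
    rr <- (idx - 1L) %% h + 1L
    cc <- (idx - 1L) %/% h + 1L
    r0 <- max(1L, min(rr) - rpx - 1L); r1 <- min(h, max(rr) + rpx + 1L)
    c0 <- max(1L, min(cc) - rpx - 1L); c1 <- min(w, max(cc) + rpx + 1L)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == id
    # Euclidean dilation: distance of every non-vessel pixel to the vessel
    d <- .asMat(EBImage::distmap(!sub))
    marker <- sub | (d <= rpx)
    markers[[i]] <- data.frame(
      parentId = id, x = tmemSet@vessels$x[i], y = tmemSet@vessels$y[i],
      markerAreaUm2 = sum(marker) * mpp^2)
    masks[[i]] <- list(r0 = r0, c0 = c0, mask = marker)
  }
  methods::initialize(tmemSet,
    markers = if (length(markers)) do.call(rbind, markers) else
      .emptyMarkers(),
    markerMasks = masks)
}
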