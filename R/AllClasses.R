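#' Five-class pixel label scheme
#'
#' Ordered class codes used by the pixel classifier: macrophage (DAB/CD68),
#' darkly and lightly stained tumor cells (Fast Red/pan-Mena), blood vessel
#' (Vector Blue/CD31), and stroma/background (light green counterstain).
#' Two tumor classes accommodate variation in staining intensity; they are
#' merged before morphometry.
#'
#' @return Named integer vector of the five stable class codes.
#' @export
labelScheme <- function() {
  c(MACROPHAGE = 1L, TUMOR_DARK = 2L, TUMOR_LIGHT = 3L, VESSEL = 4L,
    STROMA = 5L)
}

#' @noRd
.mergedClasses <- function() c("TUMOR", "STROMA", "VESSEL", "MACROPHAGE")

#' Physical calibration of a slide image
#'
#' Holds the physical pixel size and the high-power-field (HPF) tile
#' dimensions used for scoring. The default pixel size of 0.357 um/px is the
#' scale at which a 50 um dilation equals 140 px; scanners differ, so the
#' value is always configurable (use `mpp` to override). HPF presets:
#' 300 x 400 um (default, automated scoring grid) or 439 x 330 um (the
#' manual-microscopy field).
#'
#' @slot mpp microns per pixel (> 0).
#' @slot tileWidthUm,tileHeightUm HPF tile dimensions in microns (> 0).
#' @export
setClass("CalibrationParams", representation(
  mpp = "numeric", tileWidthUm = "numeric", tileHeightUm = "numeric"))

setValidity("CalibrationParams", function(object) {
  if (length(object@mpp) != 1 || !is.finite(object@mpp) || object@mpp <= 0)
    return("microns_per_pixel must be a single positive number")
  if (object@tileWidthUm <= 0 || object@tileHeightUm <= 0)
    return("tile dimensions must be positive")
  TRUE
})

#' @param mpp microns per pixel.
#' @param tileWidthUm,tileHeightUm HPF tile dimensions in microns.
#' @rdname CalibrationParams-class
#' @export
calibrationParams <- function(mpp = 0.357, tileWidthUm = 300,
                              tileHeightUm = 400) {
  methods::new("CalibrationParams", mpp = mpp, tileWidthUm = tileWidthUm,
               tileHeightUm = tileHeightUm)
}

#' Morphometric thresholds of the TMEM reclassification cascade
#'
#' All areas are in um^2 and all contacts are perimeter fractions in [0, 1];
#' they are converted to pixels via [calibrationParams()]. Defaults are the
#' published algorithm constants: vessel/macrophage aggregates larger than
#' 800 um^2 are removed, as are tumor fragments < 10 um^2, stroma
#' < 400 um^2, and macrophage or vessel particles < 5 um^2 (removal uses
#' strict inequalities, so an object of exactly 800 or exactly 5 um^2 is
#' kept). Cascade gates use "at least" (>=) semantics: 2% vessel-macrophage
#' contact; large (>= 40 um^2) macrophage-vessel complexes need >= 8% tumor
#' and >= 20% vessel contact, small ones (< 40 um^2) >= 10% and >= 10%;
#' TMEM-associated vessels need >= 20% tumor and >= 20% TA-macrophage
#' contact. TMEM marker objects are TA-vessels dilated by 50 um.
#'
#' @slot maxVesselOrMacAggregateUm2,minTumorFragmentUm2,minStromaUm2,minMacrophageUm2,minVesselUm2 size filters (um^2).
#' @slot vesselMacContactMin,largeMacTumorContactMin,largeMacVesselContactMin,smallMacTumorContactMin,smallMacVesselContactMin,taVesselTumorContactMin,taVesselMacContactMin contact-fraction gates.
#' @slot largeMacThresholdUm2 large/small macrophage split (um^2).
#' @slot tmemDilationUm TMEM marker dilation radius (um).
#' @slot smoothingRadiusUm radius of the boundary-smoothing morphological
#'   closing (um); the dilate-then-erode step applied per class mask.
#' @export
setClass("MorphometryParams", representation(
  maxVesselOrMacAggregateUm2 = "numeric",
  minTumorFragmentUm2 = "numeric",
  minStromaUm2 = "numeric",
  minMacrophageUm2 = "numeric",
  minVesselUm2 = "numeric",
  vesselMacContactMin = "numeric",
  largeMacThresholdUm2 = "numeric",
  largeMacTumorContactMin = "numeric",
  largeMacVesselContactMin = "numeric",
  smallMacTumorContactMin = "numeric",
  smallMacVesselContactMin = "numeric",
  taVesselTumorContactMin = "numeric",
  taVesselMacContactMin = "numeric",
  tmemDilationUm = "numeric",
  smoothingRadiusUm = "numeric"))

setValidity("MorphometryParams", function(object) {
  areas <- c(object@maxVesselOrMacAggregateUm2, object@minTumorFragmentUm2,
             object@minStromaUm2, object@minMacrophageUm2,
             object@minVesselUm2, object@largeMacThresholdUm2)
  if (any(!is.finite(areas)) || any(areas <= 0))
    return("all area thresholds must be positive")
  fr <- c(object@vesselMacContactMin, object@largeMacTumorContactMin,
          object@largeMacVesselContactMin, object@smallMacTumorContactMin,
          object@smallMacVesselContactMin, object@taVesselTumorContactMin,
          object@taVesselMacContactMin)
  if (any(fr < 0) || any(fr > 1))
    return("contact fractions must lie in [0, 1]")
  if (object@tmemDilationUm <= 0) return("tmemDilationUm must be positive")
  if (object@smoothingRadiusUm < 0)
    return("smoothingRadiusUm must be non-negative")
  TRUE
})

#' @param ... named overrides of the defaults documented above.
#' @rdname MorphometryParams-class
#' @export
morphometryParams <- function(...) {
  defaults <- list(
    maxVesselOrMacAggregateUm2 = 800, minTumorFragmentUm2 = 10,
    minStromaUm2 = 400, minMacrophageUm2 = 5, minVesselUm2 = 5,
    vesselMacContactMin = 0.02, largeMacThresholdUm2 = 40,
    largeMacTumorContactMin = 0.08, largeMacVesselContactMin = 0.20,
    smallMacTumorContactMin = 0.10, smallMacVesselContactMin = 0.10,
    taVesselTumorContactMin = 0.20, taVesselMacContactMin = 0.20,
    tmemDilationUm = 50, smoothingRadiusUm = 0.75)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown morphometry parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(methods::new, c(list("MorphometryParams"), defaults))
}

#' Field ranking parameters
#'
#' @slot topK number of highest-ranked HPF tiles summed into the score
#'   (default 10).
#' @slot minTileRoiOverlap minimum fraction of a tile that must be covered
#'   by the ROI for the tile to enter the ranking (default 0.5).
#' @export
setClass("ScoringParams", representation(
  topK = "integer", minTileRoiOverlap = "numeric"))

setValidity("ScoringParams", function(object) {
  if (object@topK < 1L) return("topK must be >= 1")
  if (object@minTileRoiOverlap < 0 || object@minTileRoiOverlap > 1)
    return("minTileRoiOverlap must lie in [0, 1]")
  TRUE
})

#' @param topK,minTileRoiOverlap see slot documentation.
#' @rdname ScoringParams-class
#' @export
scoringParams <- function(topK = 10L, minTileRoiOverlap = 0.5) {
  methods::new("ScoringParams", topK = as.integer(topK),
               minTileRoiOverlap = minTileRoiOverlap)
}

#' Risk category cutoffs
#'
#' TMEM score cutoffs separating low, intermediate, and high metastatic
#' risk. Defaults 6 and 23 (score units). Boundary convention (exposed, not
#' implied by the cutoffs themselves): low if score <= lowCutoff, high if
#' score > highCutoff, intermediate otherwise.
#'
#' @slot lowCutoff,highCutoff score cutoffs with lowCutoff < highCutoff.
#' @export
setClass("RiskParams", representation(
  lowCutoff = "numeric", highCutoff = "numeric"))

setValidity("RiskParams", function(object) {
  if (object@lowCutoff >= object@highCutoff)
    return("lowCutoff must be < highCutoff")
  TRUE
})

#' @param lowCutoff,highCutoff score cutoffs.
#' @rdname RiskParams-class
#' @export
riskParams <- function(lowCutoff = 6, highCutoff = 23) {
  methods::new("RiskParams", lowCutoff = lowCutoff, highCutoff = highCutoff)
}

#' Stain color-direction matrix
#'
#' One unit color-direction vector in optical-density space per stain:
#' vessel stain (Vector Blue / CD31), macrophage stain (DAB / CD68), tumor
#' stain (Fast Red / pan-Mena), and the light-green counterstain. Modeling
#' the counterstain as a fourth direction keeps background from bleeding
#' into the three signal channels.
#'
#' @slot od 3 x k matrix of unit OD direction column vectors (k >= 2,
#'   rank = min(3, k)); column names are the stain names.
#' @slot reference 3 x k matrix of the 8-bit RGB reference colors the
#'   directions were derived from (provenance only).
#' @export
setClass("StainMatrix", representation(od = "matrix", reference = "matrix"))

setValidity("StainMatrix", function(object) {
  M <- object@od
  if (nrow(M) != 3) return("od matrix must have 3 rows (R, G, B)")
  if (ncol(M) < 2) return("need at least 2 stains")
  if (any(M < -1e-12)) return("stain OD vectors must be non-negative")
  nrm <- sqrt(colSums(M^2))
  if (any(abs(nrm - 1) > 1e-8)) return("stain OD vectors must be unit norm")
  if (qr(M)$rank < min(3, ncol(M)))
    return("stain matrix is rank deficient (stain colors too similar)")
  TRUE
})

#' Per-pixel stain feature channels
#'
#' Per-pixel stain concentrations (arbitrary units >= 0) obtained by
#' unmixing the optical-density image onto the stain directions, followed by
#' per-channel median filtering.
#'
#' @slot data H x W x k array of channel values.
#' @slot channels channel (stain) names.
#' @slot medianRadius the median-filter radius (px) that was applied.
#' @export
setClass("FeatureStack", representation(
  data = "array", channels = "character", medianRadius = "integer"))

setValidity("FeatureStack", function(object) {
  if (length(dim(object@data)) != 3) return("data must be H x W x k")
  if (dim(object@data)[3] != length(object@channels))
    return("channel names must match third dimension")
  if (any(!is.finite(object@data))) return("feature values must be finite")
  TRUE
})

#' Linear Bayesian (Gaussian LDA) pixel classifier model
#'
#' Gaussian linear discriminant model: per-class feature means, one shared
#' (pooled) covariance matrix regularized by a trace-scaled ridge, and class
#' prior probabilities. Shared covariance makes all decision boundaries
#' linear. Training is done once and the model is then frozen and applied
#' unchanged.
#'
#' @slot means K x d matrix of class means (rows named by class).
#' @slot covariance d x d regularized pooled covariance (symmetric PD).
#' @slot priors length-K prior probabilities (sum to 1).
#' @slot channels feature channel names (length d).
#' @slot classes class names in code order.
#' @slot nPerClass training sample counts per class.
#' @export
setClass("ClassifierModel", representation(
  means = "matrix", covariance = "matrix", priors = "numeric",
  channels = "character", classes = "character", nPerClass = "integer"))

setValidity("ClassifierModel", function(object) {
  K <- nrow(object@means); d <- ncol(object@means)
  if (length(object@classes) != K) return("classes must match means rows")
  if (length(object@priors) != K) return("priors must match classes")
  if (any(object@priors < 0) || abs(sum(object@priors) - 1) > 1e-8)
    return("priors must be non-negative and sum to 1")
  if (!all(dim(object@covariance) == c(d, d)))
    return("covariance must be d x d")
  if (max(abs(object@covariance - t(object@covariance))) > 1e-8)
    return("covariance must be symmetric")
  ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("covariance must be positive definite")
  if (length(object@channels) != d) return("channels must match means cols")
  TRUE
})

#' Connected tissue objects per merged class
#'
#' Result of component labelling of the smoothed class masks: one integer
#' label matrix per merged class (TUMOR, STROMA, VESSEL, MACROPHAGE) plus a
#' per-object statistics table. Object labels are stable across filtering
#' (filtered objects are blanked, not renumbered).
#'
#' @slot labels named list of integer H x W label matrices.
#' @slot stats data.frame with columns class, id, nPx, areaUm2, perimeterPx,
#'   perimeterUm, x, y (centroid, 0-based pixel-centre coordinates).
#' @slot calibration the [CalibrationParams-class] used.
#' @export
setClass("TissueObjects", representation(
  labels = "list", stats = "data.frame", calibration = "CalibrationParams"))

#' TMEM-associated objects and dilated TMEM markers
#'
#' Final result of the reclassification cascade: TMEM-associated (TA)
#' vessels and macrophages, the total TA-macrophage/TA-vessel interface
#' length, and (after [makeTmemObjects()]) one dilated TMEM marker object
#' per TA-vessel. Each marker derives from exactly one parent TA-vessel and
#' overlapping markers stay distinct.
#'
#' @slot vessels data.frame of TA-vessels (id, areaUm2, x, y).
#' @slot macrophages data.frame of TA-macrophages (id, size "large"/"small",
#'   areaUm2, x, y).
#' @slot vesselLab,macLab integer label matrices restricted to TA objects
#'   (labels are the original object ids).
#' @slot markers data.frame of TMEM marker objects (parentId, x, y of the
#'   parent vessel centroid, markerAreaUm2).
#' @slot markerMasks list of per-marker cropped logical masks with fields
#'   r0, c0 (1-based offsets) and mask.
#' @slot interfaceUm total TA-macrophage boundary length in contact with
#'   TA-vessels (um).
#' @slot calibration the [CalibrationParams-class] used.
#' @export
setClass("TMEMObjectSet", representation(
  vessels = "data.frame", macrophages = "data.frame",
  vesselLab = "matrix", macLab = "matrix",
  markers = "data.frame", markerMasks = "list",
  interfaceUm = "numeric", calibration = "CalibrationParams"))

setValidity("TMEMObjectSet", function(object) {
  if (nrow(object@markers) > 0 &&
      !all(object@markers$parentId %in% object@vessels$id))
    return("every TMEM marker must derive from a TA-vessel")
  TRUE
})

#' Per-case TMEM slide score
#'
#' @slot score final TMEM score: sum of TMEM object counts over the top-K
#'   ranked HPF tiles.
#' @slot risk risk category: "low", "intermediate", or "high".
#' @slot metrics the three quantification metrics: taVessels (the primary
#'   score basis), taMacrophages, and interfaceUm.
#' @slot tiles data.frame of all eligible tiles (row, col, x0, y0, wPx, hPx,
#'   roiOverlap, count, rank; rank NA outside the top-K).
#' @slot topTiles integer indices (rows of `tiles`) of the ranked top-K.
#' @slot params echo of the effective parameters for provenance.
#' @export
setClass("SlideScore", representation(
  score = "numeric", risk = "character", metrics = "numeric",
  tiles = "data.frame", topTiles = "integer", params = "list"))

setValidity("SlideScore", function(object) {
  if (length(object@topTiles) &&
      abs(object@score - sum(object@tiles$count[object@topTiles])) > 1e-9)
    return("score must equal the sum of the top-K tile counts")
  if (!object@risk %in% c("low", "intermediate", "high"))
    return("risk must be low/intermediate/high")
  TRUE
})

#' Synthetic slide specification
#'
#' Describes a synthetic triple-IHC-like slide: canvas size, physical
#' scale, number of planted TMEM triads, distractor counts by kind, stain
#' palette, additive RGB noise level, and the RNG seed. Planted structures
#' are placed on a site grid whose pitch guarantees pairwise edge
#' separation > 2 x (50 um + smoothing radius), so markers and contacts of
#' different structures never interact; a spec too dense to honor this is
#' rejected.
#'
#' @slot dims canvas height and width in px.
#' @slot mpp microns per pixel.
#' @slot nTriads number of planted TMEM triads.
#' @slot distractors named integer vector with kinds isolated_mac,
#'   vessel_no_mac, no_tumor_contact, aggregate, fragment; each violates
#'   exactly one cascade gate.
#' @slot palette 5 x 3 integer matrix of 8-bit RGB colors, rows in
#'   [labelScheme()] order.
#' @slot noiseSd additive Gaussian RGB noise sd (8-bit units), applied after
#'   geometry so class boundaries never move.
#' @slot seed RNG seed; generation is a pure function of the spec.
#' @export
setClass("SlideSpec", representation(
  dims = "integer", mpp = "numeric", nTriads = "integer",
  distractors = "integer", palette = "matrix", noiseSd = "numeric",
  seed = "integer"))

setValidity("SlideSpec", function(object) {
  if (length(object@dims) != 2 || any(object@dims < 64))
    return("dims must be two values >= 64")
  if (object@nTriads < 0) return("nTriads must be >= 0")
  kinds <- c("isolated_mac", "vessel_no_mac", "no_tumor_contact",
             "aggregate", "fragment")
  if (!identical(sort(names(object@distractors)), sort(kinds)))
    return("distractors must be named by the five kinds")
  if (any(object@distractors < 0)) return("distractor counts must be >= 0")
  if (!all(dim(object@palette) == c(5, 3)))
    return("palette must be 5 x 3 (RGB per class)")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Ground truth of a synthetic slide
#'
#' @slot triads data.frame of planted triads (site coordinates, vessel
#'   centroid, areas, and the discretely measured template contact
#'   fractions).
#' @slot distractors data.frame of planted distractors (kind, y, x).
#' @slot expectedCount number of planted triads whose constructed contacts
#'   meet every cascade gate (= all of them, by builder self-check).
#' @slot labelMask integer H x W raster of true class codes
#'   ([labelScheme()]).
#' @export
setClass("GroundTruth", representation(
  triads = "data.frame", distractors = "data.frame",
  expectedCount = "integer", labelMask = "matrix"))

#' Full pipeline configuration
#'
#' Aggregates calibration, morphometry, scoring, and risk parameters with
#' the stain matrix, the median-filter radius, and an optional classifier
#' model path. Read and written as YAML by [readConfig()]/[writeConfig()].
#'
#' @slot calibration a [CalibrationParams-class].
#' @slot morphometry a [MorphometryParams-class].
#' @slot scoring a [ScoringParams-class].
#' @slot risk a [RiskParams-class].
#' @slot stains a [StainMatrix-class].
#' @slot medianRadius median filter radius in px (>= 0).
#' @slot classifierPath path to a classifier model JSON ("" if unset).
#' @slot verbosity 0 = quiet, 1 = stage log lines.
#' @export
setClass("TMEMConfig", representation(
  calibration = "CalibrationParams", morphometry = "MorphometryParams",
  scoring = "ScoringParams", risk = "RiskParams", stains = "StainMatrix",
  medianRadius = "integer", classifierPath = "character",
  verbosity = "integer"))

setValidity("TMEMConfig", function(object) {
  if (object@medianRadius < 0L) return("medianRadius must be >= 0")
  TRUE
})
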