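#' @title Accessors for pipeline result objects
#' @description Accessor generics for [SlideScore-class],
#'   [TMEMObjectSet-class], [GroundTruth-class], and [FeatureStack-class]
#'   objects; use these rather than reaching into slots.
#' @param x a result object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tmemScore", function(x) standardGeneric("tmemScore"))

#' @rdname accessors
#' @export
setGeneric("riskCategory", function(x) standardGeneric("riskCategory"))

#' @rdname accessors
#' @export
setGeneric("tmemMetrics", function(x) standardGeneric("tmemMetrics"))

#' @rdname accessors
#' @export
setGeneric("tileCounts", function(x) standardGeneric("tileCounts"))

#' @rdname accessors
#' @export
setGeneric("taVessels", function(x) standardGeneric("taVessels"))

#' @rdname accessors
#' @export
setGeneric("taMacrophages", function(x) standardGeneric("taMacrophages"))

#' @rdname accessors
#' @export
setGeneric("tmemMarkers", function(x) standardGeneric("tmemMarkers"))

#' @rdname accessors
#' @export
setGeneric("interfaceLength", function(x) standardGeneric("interfaceLength"))

#' @rdname accessors
#' @export
setGeneric("expectedCount", function(x) standardGeneric("expectedCount"))

#' @rdname accessors
#' @export
setGeneric("featureChannels", function(x) standardGeneric("featureChannels"))

#' @rdname accessors
#' @export
setMethod("tmemScore", "SlideScore", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("riskCategory", "SlideScore", function(x) x@risk)

#' @rdname accessors
#' @export
setMethod("tmemMetrics", "SlideScore", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("tileCounts", "SlideScore", function(x) x@tiles)

#' @rdname accessors
#' @export
setMethod("taVessels", "TMEMObjectSet", function(x) x@vessels)

#' @rdname accessors
#' @export
setMethod("taMacrophages", "TMEMObjectSet", function(x) x@macrophages)

#' @rdname accessors
#' @export
setMethod("tmemMarkers", "TMEMObjectSet", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("interfaceLength", "TMEMObjectSet", function(x) x@interfaceUm)

#' @rdname accessors
#' @export
setMethod("expectedCount", "GroundTruth", function(x) x@expectedCount)

#' @rdname accessors
#' @export
setMethod("featureChannels", "FeatureStack", function(x) x@channels)

setMethod("show", "CalibrationParams", function(object) {
  cat(sprintf("CalibrationParams: %.4g um/px, HPF %g x %g um\n",
              object@mpp, object@tileWidthUm, object@tileHeightUm))
})

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix with", ncol(object@od), "stains:",
      paste(colnames(object@od), collapse = ", "), "\n")
  print(round(object@od, 3))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureStack: %d x %d px, %d channels (%s), median radius %d\n",
              d[1], d[2], d[3], paste(object@channels, collapse = ", "),
              object@medianRadius))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel (linear Bayesian / Gaussian LDA): %d classes, %d features\n",
    nrow(object@means), ncol(object@means)))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  training n:", paste(object@nPerClass, collapse = ", "), "\n")
})

setMethod("show", "TissueObjects", function(object) {
  tb <- table(factor(object@stats$class, levels = .mergedClasses()))
  cat("TissueObjects:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
})

setMethod("show", "TMEMObjectSet", function(object) {
  cat(sprintf(
    "TMEMObjectSet: %d TA-vessels, %d TA-macrophages, interface %.1f um, %d markers\n",
    nrow(object@vessels), nrow(object@macrophages), object@interfaceUm,
    nrow(object@markers)))
})

setMethod("show", "SlideScore", function(object) {
  cat(sprintf("SlideScore: %g (risk: %s)\n", object@score, object@risk))
  cat(sprintf("  metrics: TA-vessels %g, TA-macrophages %g, interface %.1f um\n",
              object@metrics[["taVessels"]], object@metrics[["taMacrophages"]],
              object@metrics[["interfaceUm"]]))
  cat(sprintf("  %d eligible tiles, top %d summed\n", nrow(object@tiles),
              length(object@topTiles)))
})

setMethod("show", "SlideSpec", function(object) {
  cat(sprintf(
    "SlideSpec: %d x %d px @ %.3f um/px, %d triads, %d distractors, noise sd %g, seed %d\n",
    object@dims[1], object@dims[2], object@mpp, object@nTriads,
    sum(object@distractors), object@noiseSd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted triads (expected count %d), %d distractors\n",
              nrow(object@triads), object@expectedCount,
              nrow(object@distractors)))
})

setMethod("show", "TMEMConfig", function(object) {
  cat("TMEMConfig\n")
  cat(sprintf("  calibration: %.4g um/px, HPF %g x %g um\n",
              object@calibration@mpp, object@calibration@tileWidthUm,
              object@calibration@tileHeightUm))
  cat(sprintf("  scoring: top %d tiles, min ROI overlap %g\n",
              object@scoring@topK, object@scoring@minTileRoiOverlap))
  cat(sprintf("  risk cutoffs: low <= %g < intermediate <= %g < high\n",
              object@risk@lowCutoff, object@risk@highCutoff))
  cat(sprintf("  stains: %s; median radius %d px\n",
              paste(colnames(object@stains@od), collapse = ", "),
              object@medianRadius))
})
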