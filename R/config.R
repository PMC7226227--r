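# Configuration management: one YAML file carries every tunable of the
# pipeline (the published thresholds are the algorithm, so provenance is
# explicit: reports echo the effective parameters and the config hash).

#' Construct a pipeline configuration
#'
#' @param calibration a [CalibrationParams-class].
#' @param morphometry a [MorphometryParams-class].
#' @param scoring a [ScoringParams-class].
#' @param risk a [RiskParams-class].
#' @param stains a [StainMatrix-class].
#' @param medianRadius median filter radius in px.
#' @param classifierPath path to a trained classifier JSON ("" if unset).
#' @param verbosity 0 = quiet, 1 = stage log lines.
#' @return a [TMEMConfig-class].
#' @export
tmemConfig <- function(calibration = calibrationParams(),
                       morphometry = morphometryParams(),
                       scoring = scoringParams(),
                       risk = riskParams(),
                       stains = defaultStainMatrix(),
                       medianRadius = 1L,
                       classifierPath = "",
                       verbosity = 0L) {
  methods::new("TMEMConfig", calibration = calibration,
               morphometry = morphometry, scoring = scoring, risk = risk,
               stains = stains, medianRadius = as.integer(medianRadius),
               classifierPath = classifierPath,
               verbosity = as.integer(verbosity))
}

#' Default configuration
#'
#' All published algorithm constants at the default calibration of
#' 0.357 um/px (the scale at which the 50 um marker dilation is 140 px).
#'
#' @param ... overrides forwarded to [tmemConfig()].
#' @return a [TMEMConfig-class].
#' @export
defaultConfig <- function(...) tmemConfig(...)

#' @noRd
.morphometryAsList <- function(m) {
  list(
    max_vessel_or_mac_aggregate_um2 = m@maxVesselOrMacAggregateUm2,
    min_tumor_fragment_um2 = m@minTumorFragmentUm2,
    min_stroma_um2 = m@minStromaUm2,
    min_macrophage_um2 = m@minMacrophageUm2,
    min_vessel_um2 = m@minVesselUm2,
    vessel_mac_contact_min = m@vesselMacContactMin,
    large_mac_threshold_um2 = m@largeMacThresholdUm2,
    large_mac_tumor_contact_min = m@largeMacTumorContactMin,
    large_mac_vessel_contact_min = m@largeMacVesselContactMin,
    small_mac_tumor_contact_min = m@smallMacTumorContactMin,
    small_mac_vessel_contact_min = m@smallMacVesselContactMin,
    ta_vessel_tumor_contact_min = m@taVesselTumorContactMin,
    ta_vessel_mac_contact_min = m@taVesselMacContactMin,
    tmem_dilation_um = m@tmemDilationUm,
    smoothing_radius_um = m@smoothingRadiusUm)
}

#' @noRd
.configAsList <- function(config) {
  stains <- config@stains@reference
  list(
    calibration = list(
      microns_per_pixel = config@calibration@mpp,
      tile_width_um = config@calibration@tileWidthUm,
      tile_height_um = config@calibration@tileHeightUm),
    morphometry = .morphometryAsList(config@morphometry),
    scoring = list(
      top_k = config@scoring@topK,
      min_tile_roi_overlap = config@scoring@minTileRoiOverlap),
    risk = list(
      low_cutoff = config@risk@lowCutoff,
      high_cutoff = config@risk@highCutoff),
    stains = stats::setNames(
      lapply(seq_len(ncol(stains)), function(j) as.integer(stains[, j])),
      colnames(stains)),
    median_radius = config@medianRadius,
    classifier = config@classifierPath,
    verbosity = config@verbosity)
}

#' Write a configuration to YAML
#'
#' @param config a [TMEMConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Unknown keys at any level are rejected so typos cannot silently fall
#' back to defaults; omitted keys keep their defaults. The loaded
#' configuration round-trips: load, echo, and load again give identical
#' effective parameters.
#'
#' @param path path to a YAML config.
#' @return a [TMEMConfig-class].
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  ref <- .configAsList(defaultConfig())
  checkKeys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
  }
  checkKeys(y, names(ref), "top level")
  for (sec in c("calibration", "morphometry", "scoring", "risk"))
    if (!is.null(y[[sec]])) checkKeys(y[[sec]], names(ref[[sec]]), sec)
  g <- function(sec, key) y[[sec]][[key]] %||% ref[[sec]][[key]]
  stains <- if (!is.null(y$stains)) stainMatrix(y$stains)
            else defaultStainMatrix()
  tmemConfig(
    calibration = calibrationParams(
      mpp = g("calibration", "microns_per_pixel"),
      tileWidthUm = g("calibration", "tile_width_um"),
      tileHeightUm = g("calibration", "tile_height_um")),
    morphometry = morphometryParams(
      maxVesselOrMacAggregateUm2 = g("morphometry", "max_vessel_or_mac_aggregate_um2"),
      minTumorFragmentUm2 = g("morphometry", "min_tumor_fragment_um2"),
      minStromaUm2 = g("morphometry", "min_stroma_um2"),
      minMacrophageUm2 = g("morphometry", "min_macrophage_um2"),
      minVesselUm2 = g("morphometry", "min_vessel_um2"),
      vesselMacContactMin = g("morphometry", "vessel_mac_contact_min"),
      largeMacThresholdUm2 = g("morphometry", "large_mac_threshold_um2"),
      largeMacTumorContactMin = g("morphometry", "large_mac_tumor_contact_min"),
      largeMacVesselContactMin = g("morphometry", "large_mac_vessel_contact_min"),
      smallMacTumorContactMin = g("morphometry", "small_mac_tumor_contact_min"),
      smallMacVesselContactMin = g("morphometry", "small_mac_vessel_contact_min"),
      taVesselTumorContactMin = g("morphometry", "ta_vessel_tumor_contact_min"),
      taVesselMacContactMin = g("morphometry", "ta_vessel_mac_contact_min"),
      tmemDilationUm = g("morphometry", "tmem_dilation_um"),
      smoothingRadiusUm = g("morphometry", "smoothing_radius_um")),
    scoring = scoringParams(
      topK = g("scoring", "top_k"),
      minTileRoiOverlap = g("scoring", "min_tile_roi_overlap")),
    risk = riskParams(
      lowCutoff = g("risk", "low_cutoff"),
      highCutoff = g("risk", "high_cutoff")),
    stains = stains,
    medianRadius = y$median_radius %||% ref$median_radius,
    classifierPath = y$classifier %||% "",
    verbosity = y$verbosity %||% 0L)
}

#' Hash of the effective configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every report for
#' provenance.
#'
#' @param config a [TMEMConfig-class].
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeConfig(config, tf)
  unname(tools::md5sum(tf))
}
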