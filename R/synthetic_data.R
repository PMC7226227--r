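# Synthetic triple-IHC slide generator: stroma background, two-tone tumor
# nests, blue vessels and brown macrophages rendered as exact (alias-free)
# discrete shapes, with planted TMEM triads whose contact fractions clear
# every cascade gate with >= 2x margin, distractors that each violate
# exactly one gate, per-pixel ground-truth label masks, and known counts.

#' Default synthetic stain palette
#'
#' Arbitrary RGB stand-ins for Vector Blue (vessels), DAB (macrophages),
#' Fast Red (tumor, two tones), and the light-green counterstain.
#'
#' @return 5 x 3 integer matrix, rows in [labelScheme()] order.
#' @export
defaultPalette <- function() {
  pal <- rbind(
    MACROPHAGE  = c(120L,  80L,  30L),
    TUMOR_DARK  = c(200L,  60L,  90L),
    TUMOR_LIGHT = c(230L, 150L, 180L),
    VESSEL      = c( 70L,  90L, 200L),
    STROMA      = c(200L, 230L, 200L))
  colnames(pal) <- c("R", "G", "B")
  pal
}

#' @noRd
.distractorKinds <- function() {
  c("isolated_mac", "vessel_no_mac", "no_tumor_contact", "aggregate",
    "fragment")
}

#' Construct a synthetic slide specification
#'
#' @param nTriads number of planted TMEM triads.
#' @param distractors named counts for the kinds in
#'   `isolated_mac, vessel_no_mac, no_tumor_contact, aggregate, fragment`
#'   (missing kinds default to 0).
#' @param dims canvas c(height, width) in px; the default is exactly 2 x 3
#'   HPF tiles of 300 x 400 um at the default calibration.
#' @param mpp microns per pixel.
#' @param noiseSd additive Gaussian RGB noise sd (8-bit units).
#' @param seed RNG seed.
#' @param palette 5 x 3 RGB palette (rows in [labelScheme()] order).
#' @return a [SlideSpec-class].
#' @export
slideSpec <- function(nTriads = 5L,
                      distractors = c(isolated_mac = 1L, vessel_no_mac = 1L,
                                      no_tumor_contact = 1L, aggregate = 1L,
                                      fragment = 1L),
                      dims = c(2240L, 2520L), mpp = 0.357, noiseSd = 8,
                      seed = 1L, palette = defaultPalette()) {
  kinds <- .distractorKinds()
  d <- stats::setNames(integer(length(kinds)), kinds)
  if (length(distractors)) d[names(distractors)] <- as.integer(distractors)
  methods::new("SlideSpec", dims = as.integer(dims), mpp = mpp,
               nTriads = as.integer(nTriads), distractors = d,
               palette = palette, noiseSd = noiseSd,
               seed = as.integer(seed))
}

# structure geometry in um (areas chosen to sit well inside every size
# gate: vessel 50 um^2, macrophage 25 um^2, tumor nest radius 16 um)
#' @noRd
.triadGeom <- function() {
  rv <- sqrt(50 / pi)                 # vessel disk radius
  rm1 <- sqrt(rv^2 + 2 * 25 / pi)     # macrophage half-annulus outer radius
  list(nestR = 16, vesselR = rv, macR0 = rv, macR1 = rm1,
       macDiskR = sqrt(25 / pi), aggNestR = 24, aggMacR = sqrt(1000 / pi),
       fragVesselR = sqrt(3 / pi))
}

# paint one structure centred at (cy, cx) px; codes per labelScheme()
#' @noRd
.paintStructure <- function(lab, kind, cy, cx, mpp) {
  g <- .triadGeom()
  um <- function(x) x / mpp
  sch <- labelScheme()
  nest <- function(lab, R) {
    lab <- .paintDisk(lab, cy, cx, um(R), sch[["TUMOR_LIGHT"]])
    # left half dark to exercise both tumor classes
    h <- nrow(lab); w <- ncol(lab)
    rs <- max(1L, floor(cy - um(R))):min(h, ceiling(cy + um(R)))
    cs <- max(1L, floor(cx - um(R))):min(w, floor(cx))
    if (length(rs) && length(cs)) {
      d2 <- outer((rs - cy)^2, (cs - cx)^2, "+")
      sub <- lab[rs, cs, drop = FALSE]
      sub[d2 <= um(R)^2 & sub == sch[["TUMOR_LIGHT"]]] <- sch[["TUMOR_DARK"]]
      lab[rs, cs] <- sub
    }
    lab
  }
  switch(kind,
    triad = {
      lab <- nest(lab, g$nestR)
      lab <- .paintHalfAnnulus(lab, cy, cx, um(g$macR0), um(g$macR1),
                               sch[["MACROPHAGE"]], upper = TRUE)
      .paintDisk(lab, cy, cx, um(g$vesselR), sch[["VESSEL"]])
    },
    isolated_mac = {
      lab <- nest(lab, g$nestR)
      .paintDisk(lab, cy, cx, um(g$macDiskR), sch[["MACROPHAGE"]])
    },
    vessel_no_mac = {
      lab <- nest(lab, g$nestR)
      .paintDisk(lab, cy, cx, um(g$vesselR), sch[["VESSEL"]])
    },
    no_tumor_contact = {
      lab <- .paintHalfAnnulus(lab, cy, cx, um(g$macR0), um(g$macR1),
                               sch[["MACROPHAGE"]], upper = TRUE)
      .paintDisk(lab, cy, cx, um(g$vesselR), sch[["VESSEL"]])
    },
    aggregate = {
      lab <- nest(lab, g$aggNestR)
      lab <- .paintDisk(lab, cy, cx, um(g$aggMacR), sch[["MACROPHAGE"]])
      # vessel half-embedded in the aggregate's rim
      .paintDisk(lab, cy, cx + um(g$aggMacR), um(g$vesselR), sch[["VESSEL"]])
    },
    fragment = {
      lab <- nest(lab, g$nestR)
      lab <- .paintDisk(lab, cy, cx, um(g$macDiskR), sch[["MACROPHAGE"]])
      # sub-threshold vessel particle touching the macrophage
      .paintDisk(lab, cy, cx + um(g$macDiskR + g$fragVesselR) - 1,
                 um(g$fragVesselR), sch[["VESSEL"]])
    },
    stop("unknown structure kind: ", kind))
}

#' @noRd
.structureRadiusUm <- function(kind) {
  g <- .triadGeom()
  switch(kind,
    triad = , isolated_mac = , vessel_no_mac = , fragment = g$nestR,
    no_tumor_contact = g$macR1,
    aggregate = g$aggNestR)
}

# discrete self-check of the triad template: every cascade-relevant
# contact fraction must clear its gate with >= 2x margin at this
# calibration, measured by the package's own adjacency oracle
#' @noRd
.verifyTriadTemplate <- function(mpp, params = morphometryParams()) {
  g <- .triadGeom()
  half <- ceiling(g$nestR / mpp) + 4L
  side <- 2L * half + 1L
  lab <- matrix(labelScheme()[["STROMA"]], side, side)
  lab <- .paintStructure(lab, "triad", half + 1, half + 1, mpp)
  sch <- labelScheme()
  vessel <- lab == sch[["VESSEL"]]
  mac <- lab == sch[["MACROPHAGE"]]
  tumor <- lab == sch[["TUMOR_DARK"]] | lab == sch[["TUMOR_LIGHT"]]
  f <- c(
    vesselMac = contactFraction(vessel, mac),
    vesselTumor = contactFraction(vessel, tumor),
    macTumor = contactFraction(mac, tumor),
    macVessel = contactFraction(mac, vessel))
  gates <- c(
    vesselMac = max(params@vesselMacContactMin, params@taVesselMacContactMin),
    vesselTumor = params@taVesselTumorContactMin,
    macTumor = params@smallMacTumorContactMin,
    macVessel = params@smallMacVesselContactMin)
  if (any(f < 2 * gates))
    stop("triad template fails the 2x contact-margin self-check at mpp = ",
         mpp, ": ", paste(names(f), round(f, 3), collapse = ", "))
  macArea <- sum(mac) * mpp^2
  vesselArea <- sum(vessel) * mpp^2
  if (macArea < 2 * params@minMacrophageUm2 ||
      macArea >= params@largeMacThresholdUm2)
    stop("triad macrophage area ", round(macArea, 1),
         " um^2 outside the small-macrophage design range")
  if (vesselArea < 2 * params@minVesselUm2 ||
      vesselArea > params@maxVesselOrMacAggregateUm2 / 2)
    stop("triad vessel area outside the design range")
  c(f, macAreaUm2 = macArea, vesselAreaUm2 = vesselArea)
}

#' Generate a synthetic slide
#'
#' Renders the slide described by the spec: light-green stroma background,
#' two-tone tumor nests, and the planted triads/distractors on a site grid
#' whose pitch keeps all structures' edges separated by more than
#' 2 x (marker dilation + smoothing radius). Triad sites are drawn at
#' random (seeded) from the interior sites; distractors occupy the sites
#' farthest from the canvas centre. The triad template is re-verified at
#' this calibration with the package's own contact oracle before anything
#' is rendered. Additive RGB noise is applied after geometry, so the
#' ground-truth label mask is exact. Generation is a pure function of the
#' spec: the same spec gives a bit-identical slide.
#'
#' @param spec a [SlideSpec-class].
#' @param params a [MorphometryParams-class] (gates for the template
#'   self-check and the separation invariant).
#' @return list with `image` (integer H x W x 3), `labelMask` (integer
#'   H x W, [labelScheme()] codes), and `truth` (a [GroundTruth-class]).
#' @export
generateSlide <- function(spec, params = morphometryParams()) {
  methods::validObject(spec)
  tmpl <- .verifyTriadTemplate(spec@mpp, params)
  h <- spec@dims[1]; w <- spec@dims[2]
  pitchPx <- round(143 / spec@mpp)           # ~143 um site pitch
  marginPx <- round(36 / spec@mpp)
  nDistr <- sum(spec@distractors)
  nNeed <- spec@nTriads + nDistr
  nRows <- max(0L, floor((h - 2 * marginPx) / pitchPx) + 1L)
  nCols <- max(0L, floor((w - 2 * marginPx) / pitchPx) + 1L)
  if (nNeed > nRows * nCols)
    stop("spec too dense: ", nNeed, " structures but only ", nRows * nCols,
         " sites honor the separation invariant on this canvas")
  lab <- matrix(labelScheme()[["STROMA"]], h, w)
  placed <- data.frame(kind = character(0), y = numeric(0), x = numeric(0))
  if (nNeed > 0) {
    sites <- expand.grid(
      y = marginPx + (seq_len(nRows) - 1L) * pitchPx,
      x = marginPx + (seq_len(nCols) - 1L) * pitchPx)
    # distractors at the sites farthest from the centre, triads drawn
    # at random from the rest
    d2c <- (sites$y - h / 2)^2 + (sites$x - w / 2)^2
    far <- order(-d2c)
    distrKinds <- rep(names(spec@distractors), spec@distractors)
    distrSites <- far[seq_len(nDistr)]
    rest <- setdiff(seq_len(nrow(sites)), distrSites)
    triadSites <- withr::with_seed(spec@seed,
      if (spec@nTriads > 0)
        rest[sample.int(length(rest), spec@nTriads)] else integer(0))
    placed <- rbind(
      if (nDistr > 0) data.frame(kind = distrKinds,
                                 y = sites$y[distrSites],
                                 x = sites$x[distrSites]),
      if (spec@nTriads > 0) data.frame(kind = "triad",
                                       y = sites$y[triadSites],
                                       x = sites$x[triadSites]))
    # enforce the separation invariant on the actual layout
    sep <- 2 * (params@tmemDilationUm + params@smoothingRadiusUm)
    if (nrow(placed) > 1) {
      rads <- vapply(placed$kind, .structureRadiusUm, numeric(1))
      dmat <- as.matrix(stats::dist(cbind(placed$y, placed$x))) * spec@mpp
      edge <- dmat - outer(rads, rads, "+")
      diag(edge) <- Inf
      if (min(edge) <= sep)
        stop("spec too dense: structure edge separation ",
             round(min(edge), 1), " um <= required ", sep, " um")
    }
    for (i in seq_len(nrow(placed)))
      lab <- .paintStructure(lab, placed$kind[i], placed$y[i], placed$x[i],
                             spec@mpp)
  }
  img <- .renderImage(lab, spec)
  triads <- placed[placed$kind == "triad", , drop = FALSE]
  truth <- methods::new("GroundTruth",
    triads = if (nrow(triads)) data.frame(
      y = triads$y, x = triads$x,
      vesselX = triads$x - 0.5, vesselY = triads$y - 0.5,
      macAreaUm2 = tmpl[["macAreaUm2"]],
      vesselAreaUm2 = tmpl[["vesselAreaUm2"]],
      vesselMacContact = tmpl[["vesselMac"]],
      vesselTumorContact = tmpl[["vesselTumor"]],
      macTumorContact = tmpl[["macTumor"]],
      macVesselContact = tmpl[["macVessel"]]) else
      data.frame(y = numeric(0), x = numeric(0)),
    distractors = placed[placed$kind != "triad", , drop = FALSE],
    expectedCount = spec@nTriads,
    labelMask = lab)
  list(image = img, labelMask = lab, truth = truth)
}

#' @noRd
.renderImage <- function(lab, spec) {
  h <- nrow(lab); w <- ncol(lab)
  img <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- spec@palette[lab, k]
  if (spec@noiseSd > 0) {
    noise <- withr::with_seed(spec@seed + 1L,
      array(round(stats::rnorm(h * w * 3, 0, spec@noiseSd)),
            dim = c(h, w, 3)))
    img <- img + noise
    img[img < 0L] <- 0L
    img[img > 255L] <- 255L
  }
  storage.mode(img) <- "integer"
  img
}

#' Slide spec with a canvas sized to the planted count
#'
#' Picks the smallest HPF-tile-aligned canvas preset whose site grid holds
#' the requested triads plus distractors under the separation invariant
#' (1 to 6 whole 300 x 400 um tiles at the default calibration). Keeps
#' dense panels affordable without changing any study condition other than
#' canvas area.
#'
#' @param nTriads planted TMEM triads (0..31 with default distractors).
#' @param seed RNG seed.
#' @param noiseSd additive RGB noise sd.
#' @param distractors named distractor counts (default one of each kind).
#' @return a [SlideSpec-class].
#' @export
slideSpecForCount <- function(nTriads, seed, noiseSd = 8,
                              distractors = c(isolated_mac = 1L,
                                              vessel_no_mac = 1L,
                                              no_tumor_contact = 1L,
                                              aggregate = 1L,
                                              fragment = 1L)) {
  presets <- list(c(1120L, 840L), c(1120L, 1680L), c(2240L, 1680L),
                  c(2240L, 2520L))
  need <- nTriads + sum(distractors)
  pitch <- round(143 / 0.357); margin <- round(36 / 0.357)
  for (dims in presets) {
    cap <- (floor((dims[1] - 2 * margin) / pitch) + 1L) *
      (floor((dims[2] - 2 * margin) / pitch) + 1L)
    if (need <= cap)
      return(slideSpec(nTriads = nTriads, distractors = distractors,
                       dims = dims, noiseSd = noiseSd, seed = seed))
  }
  stop("no canvas preset holds ", need, " structures")
}

#' Generate a classifier training set
#'
#' Emits paired image / label-mask fields of view, each a small canvas with
#' one planted triad (so all five classes are present), emulating
#' pathologist-annotated fields from several slides.
#'
#' @param spec a [SlideSpec-class] (palette, mpp and noise are reused; the
#'   canvas and counts are replaced by the field-of-view layout).
#' @param nImages number of fields (>= 1; default 6).
#' @return list of `list(image, labelMask)` pairs.
#' @export
generateTrainingSet <- function(spec, nImages = 6L) {
  stopifnot(nImages >= 1)
  side <- as.integer(round(170 / spec@mpp))  # one-site field of view
  lapply(seq_len(nImages), function(i) {
    s <- slideSpec(nTriads = 1L, distractors = integer(0),
                   dims = c(side, side), mpp = spec@mpp,
                   noiseSd = spec@noiseSd, seed = spec@seed + 7919L * i,
                   palette = spec@palette)
    g <- generateSlide(s)
    list(image = g$image, labelMask = g$labelMask)
  })
}
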