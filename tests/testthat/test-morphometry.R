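# mpp = 1 makes um^2 equal pixel counts, so object areas are exact
cal1 <- calibrationParams(mpp = 1)
noSmooth <- morphometryParams(smoothingRadiusUm = 0)

test_that("tumor tones merge and closing bridges sub-kernel gaps", {
  sch <- labelScheme()
  lab <- stromaCanvas(10, 10)
  lab[5, 5] <- sch[["TUMOR_DARK"]]
  lab[5, 6] <- sch[["TUMOR_LIGHT"]]
  obj <- formObjects(lab, cal1, noSmooth)
  tu <- obj@stats[obj@stats$class == "TUMOR", ]
  expect_equal(nrow(tu), 1L)
  expect_equal(tu$nPx, 2L)

  # two 5x5 vessel squares with a 1-px gap: closing with radius >= 1 px
  # bridges them into one object
  lab <- stromaCanvas(20, 30)
  lab[4:8, 3:7] <- sch[["VESSEL"]]
  lab[4:8, 9:13] <- sch[["VESSEL"]]
  apart <- formObjects(lab, cal1, noSmooth)
  expect_equal(sum(apart@stats$class == "VESSEL"), 2L)
  joined <- formObjects(lab, cal1, morphometryParams(smoothingRadiusUm = 1))
  expect_equal(sum(joined@stats$class == "VESSEL"), 1L)
})

test_that("object area equals pixel count x mpp^2 and components are 8-connected", {
  set.seed(55)
  mpp <- 0.5
  cal <- calibrationParams(mpp = mpp)
  for (rep in 1:20) {
    lab <- stromaCanvas(25, 25)
    blob <- matrix(runif(625) < 0.25, 25, 25)
    lab[blob] <- labelScheme()[["MACROPHAGE"]]
    obj <- formObjects(lab, cal, noSmooth)
    st <- obj@stats[obj@stats$class == "MACROPHAGE", ]
    expect_equal(st$areaUm2, st$nPx * mpp^2)
    expect_equal(sum(st$nPx), sum(blob))
    # object count matches a brute-force 8-connected flood fill
    expect_equal(nrow(st), max(bfComponents8(blob)))
    # per-object perimeter matches the brute-force boundary count
    labm <- obj@labels$MACROPHAGE
    for (id in st$id)
      expect_equal(st$perimeterPx[st$id == id], bfBoundaryCount(labm == id))
  }
})

test_that("size filters use strict inequalities exactly as printed", {
  sch <- labelScheme()
  mk <- function(cls, npx, mpp = 1) {
    # one rectangle-ish object of the requested pixel count
    if (cls == "TUMOR") cls <- "TUMOR_DARK"
    lab <- stromaCanvas(80, 80)
    w <- min(npx, 60)
    h <- npx %/% w
    lab[10 + seq_len(h), 10 + seq_len(w)] <- sch[[cls]]
    extra <- npx - h * w
    if (extra > 0) lab[10 + h + 1, 10 + seq_len(extra)] <- sch[[cls]]
    filterObjects(formObjects(lab, calibrationParams(mpp = mpp), noSmooth),
                  morphometryParams(smoothingRadiusUm = 0))
  }
  kept <- function(o, cls) sum(o@stats$class == cls)

  expect_equal(kept(mk("MACROPHAGE", 900), "MACROPHAGE"), 0)  # > 800 removed
  expect_equal(kept(mk("MACROPHAGE", 801), "MACROPHAGE"), 0)
  expect_equal(kept(mk("MACROPHAGE", 800), "MACROPHAGE"), 1)  # exactly 800 kept
  expect_equal(kept(mk("VESSEL", 801), "VESSEL"), 0)
  expect_equal(kept(mk("VESSEL", 800), "VESSEL"), 1)
  expect_equal(kept(mk("MACROPHAGE", 4), "MACROPHAGE"), 0)    # < 5 removed
  expect_equal(kept(mk("MACROPHAGE", 5), "MACROPHAGE"), 1)    # exactly 5 kept
  expect_equal(kept(mk("VESSEL", 4), "VESSEL"), 0)
  expect_equal(kept(mk("VESSEL", 5), "VESSEL"), 1)
  expect_equal(kept(mk("TUMOR", 9), "TUMOR"), 0)
  expect_equal(kept(mk("TUMOR", 10), "TUMOR"), 1)
  # vessel of 4.9 um^2 (10 px at 0.7 um/px) removed
  expect_equal(kept(mk("VESSEL", 10, mpp = 0.7), "VESSEL"), 0)
  # 5.39 um^2 kept
  expect_equal(kept(mk("VESSEL", 11, mpp = 0.7), "VESSEL"), 1)
  # empty object set stays empty
  empty <- filterObjects(formObjects(stromaCanvas(500, 500), cal1, noSmooth))
  expect_equal(sum(empty@stats$class != "STROMA"), 0)
})

test_that("contact fractions match the exhaustive adjacency oracle", {
  # full surround -> 1; absent neighbour -> 0
  obj <- matrix(FALSE, 9, 9); obj[4:6, 4:6] <- TRUE
  ring <- matrix(TRUE, 9, 9); ring[2:8, 2:8][obj[2:8, 2:8]] <- FALSE
  ring[obj] <- FALSE
  expect_equal(contactFraction(obj, ring), 1)
  expect_equal(contactFraction(obj, matrix(FALSE, 9, 9)), 0)
  expect_error(contactFraction(matrix(FALSE, 9, 9), ring), "empty")

  set.seed(77)
  for (rep in 1:50) {
    o <- matrix(runif(225) < 0.3, 15, 15)
    n <- matrix(runif(225) < 0.3, 15, 15) & !o
    if (!any(o)) next
    expect_equal(contactFraction(o, n), bfContactFraction(o, n)$fraction)
  }
})

test_that("a constructed triad yields exactly one TA-vessel and one small TA-macrophage", {
  lab <- stromaCanvas(300, 300)
  lab <- TMEMscore:::.paintStructure(lab, "triad", 150, 150, 0.357)
  tset <- cascadeFromLabels(lab)
  expect_equal(nrow(taVessels(tset)), 1L)
  expect_equal(nrow(taMacrophages(tset)), 1L)
  expect_equal(taMacrophages(tset)$size, "small")
  expect_gt(interfaceLength(tset), 0)
  # determinism of the whole morphometric pipeline
  tset2 <- cascadeFromLabels(lab)
  expect_equal(taVessels(tset2), taVessels(tset))
  expect_equal(tmemMarkers(tset2), tmemMarkers(tset))
  # every TA-vessel satisfied the step (a) gate (cascade consistency)
  sch <- labelScheme()
  expect_gte(contactFraction(tset@vesselLab > 0, lab == sch[["MACROPHAGE"]]),
             morphometryParams()@vesselMacContactMin)
})

test_that("sub-gate contact never produces TMEM objects", {
  sch <- labelScheme()
  # vessel square 30x30 inside tumor, macrophage blob touching only at a
  # corner: ~3 of 116 boundary px in contact (~2.6% is above the 2% gate),
  # single-pixel diagonal touch is ~0.9% (below)
  base <- stromaCanvas(200, 200)
  base[60:140, 60:140] <- sch[["TUMOR_DARK"]]
  base[80:109, 80:109] <- sch[["VESSEL"]]
  below <- base
  below[79, 79] <- sch[["MACROPHAGE"]]    # one diagonal contact pixel
  below[70:78, 70:79] <- sch[["MACROPHAGE"]]
  fBelow <- contactFraction(below == sch[["VESSEL"]],
                            below == sch[["MACROPHAGE"]])
  expect_lt(fBelow, 0.02)
  expect_equal(nrow(taVessels(cascadeFromLabels(below, cal1, noSmooth))), 0L)
})

test_that("TMEM markers are per-vessel Euclidean dilations of the stated radius", {
  # no TA-vessels -> no markers
  empty <- cascadeFromLabels(stromaCanvas(400, 400))
  expect_equal(nrow(tmemMarkers(empty)), 0L)

  # one triad: the marker is the vessel dilated by 50 um (140 px at
  # 0.357 um/px); a ~8 um vessel disk gives a ~108 um diameter marker
  lab <- stromaCanvas(500, 500)
  lab <- TMEMscore:::.paintStructure(lab, "triad", 250, 250, 0.357)
  tset <- cascadeFromLabels(lab)
  expect_equal(nrow(tmemMarkers(tset)), 1L)
  mk <- tset@markerMasks[[1]]
  widthPx <- diff(range(which(apply(mk$mask, 2, any)))) + 1
  rv <- sqrt(50 / pi)  # vessel radius um
  expect_equal(widthPx * 0.357, 2 * (50 + rv), tolerance = 0.03)
  # marker covers its parent vessel
  expect_gte(tmemMarkers(tset)$markerAreaUm2, taVessels(tset)$areaUm2)

  # brute-force Euclidean distance check on a cropped window
  vm <- tset@vesselLab[mk$r0 + seq_len(nrow(mk$mask)) - 1,
                       mk$c0 + seq_len(ncol(mk$mask)) - 1] > 0
  vidx <- which(vm, arr.ind = TRUE)
  rpx <- round(50 / 0.357)
  set.seed(9)
  probe <- cbind(sample.int(nrow(vm), 300, TRUE),
                 sample.int(ncol(vm), 300, TRUE))
  for (i in seq_len(300)) {
    d <- sqrt(min((probe[i, 1] - vidx[, 1])^2 + (probe[i, 2] - vidx[, 2])^2))
    expect_equal(mk$mask[probe[i, 1], probe[i, 2]], d <= rpx,
                 label = paste("probe", i))
  }

  # two nearby triads: two markers with distinct parents even overlapping
  lab2 <- stromaCanvas(500, 600)
  lab2 <- TMEMscore:::.paintStructure(lab2, "triad", 250, 250, 0.357)
  lab2 <- TMEMscore:::.paintStructure(lab2, "triad", 250, 420, 0.357)
  t2 <- cascadeFromLabels(lab2)
  expect_equal(nrow(tmemMarkers(t2)), 2L)
  expect_equal(length(unique(tmemMarkers(t2)$parentId)), 2L)
})

test_that("the cascade is monotone in its contact thresholds", {
  g <- generateSlide(smallSpec(4, seed = 61, noiseSd = 0))
  base <- morphometryParams()
  nBase <- nrow(taVessels(cascadeFromLabels(g$labelMask)))
  expect_equal(nBase, 4L)
  raise <- list(
    morphometryParams(vesselMacContactMin = 0.3),
    morphometryParams(smallMacTumorContactMin = 0.5),
    morphometryParams(smallMacVesselContactMin = 0.6),
    morphometryParams(taVesselTumorContactMin = 0.7),
    morphometryParams(taVesselMacContactMin = 0.9))
  for (p in raise) {
    n <- nrow(taVessels(cascadeFromLabels(g$labelMask, params = p)))
    expect_lte(n, nBase)
  }
  # raising beyond any attainable fraction empties the result
  pMax <- morphometryParams(taVesselTumorContactMin = 1)
  expect_lte(nrow(taVessels(cascadeFromLabels(g$labelMask, params = pMax))),
             nBase)
})

test_that("um^2 decisions survive a resolution doubling on ideal shapes", {
  for (mpp in c(0.357, 0.357 / 2)) {
    lab <- stromaCanvas(round(120 / mpp), round(120 / mpp))
    lab <- TMEMscore:::.paintStructure(lab, "triad", round(60 / mpp),
                                       round(60 / mpp), mpp)
    tset <- cascadeFromLabels(lab, calibrationParams(mpp = mpp))
    expect_equal(nrow(taVessels(tset)), 1L, label = paste("mpp", mpp))
    expect_equal(taMacrophages(tset)$size, "small")
  }
})
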