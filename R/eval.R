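# End-to-end evaluation harness on synthetic slides: repeatability
# (score each slide twice) and concordance of the three quantification
# metrics.

#' Evaluate the pipeline on synthetic slides
#'
#' Generates `nSlides` synthetic slides with varying planted TMEM counts,
#' trains the pixel classifier once from a generated training set (unless a
#' model is supplied), scores every slide twice, and reports per-slide
#' truth vs recovered counts, the repeatability Pearson correlation between
#' the two runs, and the pairwise Spearman matrix of the three
#' quantification metrics. When the truth counts are all equal the rank
#' correlations are undefined and reported as NA.
#'
#' @param config a [TMEMConfig-class].
#' @param nSlides number of slides (>= 3, so the correlations are defined).
#' @param seed master seed; slide seeds and planted counts derive from it.
#' @param maxTriads planted counts are drawn uniformly from 0..maxTriads.
#' @param dims slide canvas in px (default 1120 x 1680, two HPF tiles).
#' @param noiseSd RGB noise sd for the generated slides.
#' @param distractors named distractor counts per slide (see
#'   [slideSpec()]).
#' @param model optional pre-trained [ClassifierModel-class].
#' @return list with `perSlide` (data.frame: seed, truth, score1, score2,
#'   taVessels, taMacrophages, interfaceUm, risk), `repeatabilityR`,
#'   `spearman` (3 x 3 matrix or NA), and `configHash`.
#' @export
runEval <- function(config = defaultConfig(), nSlides = 12L, seed = 1L,
                    maxTriads = 6L, dims = c(1120L, 1680L), noiseSd = 8,
                    distractors = c(isolated_mac = 1L, vessel_no_mac = 1L,
                                    no_tumor_contact = 1L, aggregate = 1L,
                                    fragment = 1L),
                    model = NULL) {
  if (nSlides < 3) stop("need at least 3 slides for correlation outputs")
  counts <- withr::with_seed(seed,
    sample.int(maxTriads + 1L, nSlides, replace = TRUE) - 1L)
  if (is.null(model)) {
    trainSpec <- slideSpec(dims = dims, noiseSd = noiseSd,
                           seed = seed + 500000L)
    model <- trainPixelClassifier(
      images = lapply(ts <- generateTrainingSet(trainSpec), `[[`, "image"),
      labelMasks = lapply(ts, `[[`, "labelMask"),
      stains = config@stains, medianRadius = config@medianRadius)
  }
  rows <- lapply(seq_len(nSlides), function(i) {
    spec <- slideSpec(nTriads = counts[i], dims = dims, noiseSd = noiseSd,
                      distractors = distractors, seed = seed * 1000L + i)
    g <- generateSlide(spec, config@morphometry)
    s1 <- scoreSlide(g$image, model = model, config = config)
    s2 <- scoreSlide(g$image, model = model, config = config)
    m <- tmemMetrics(s1)
    data.frame(seed = spec@seed, truth = expectedCount(g$truth),
               score1 = tmemScore(s1), score2 = tmemScore(s2),
               taVessels = m[["taVessels"]],
               taMacrophages = m[["taMacrophages"]],
               interfaceUm = m[["interfaceUm"]],
               risk = riskCategory(s1))
  })
  perSlide <- do.call(rbind, rows)
  repeatR <- if (stats::sd(perSlide$score1) > 0 &&
                 stats::sd(perSlide$score2) > 0)
    stats::cor(perSlide$score1, perSlide$score2) else NA_real_
  mets <- as.matrix(perSlide[, c("taVessels", "taMacrophages",
                                 "interfaceUm")])
  spearman <- if (all(apply(mets, 2, stats::sd) > 0))
    stats::cor(mets, method = "spearman") else NA
  list(perSlide = perSlide, repeatabilityR = repeatR, spearman = spearman,
       configHash = configHash(config))
}
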