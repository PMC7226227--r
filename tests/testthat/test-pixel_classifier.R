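test_that("training recovers closed-form moments and handles degeneracy", {
  # two 1-D classes with zero within-class variance: variance = ridge
  m <- trainClassifier(list(a = matrix(c(0, 0)), b = matrix(c(2, 2))),
                       regularization = 1e-6)
  expect_equal(unname(m@means[, 1]), c(0, 2))
  expect_equal(m@covariance[1, 1], 1e-6)  # zero pooled cov, trace scale -> 1
  expect_equal(m@priors, c(0.5, 0.5))

  # moments match a direct formula computation on random samples
  set.seed(21)
  samples <- list(
    s1 = matrix(rnorm(20 * 3, 0), 20, 3),
    s2 = matrix(rnorm(15 * 3, 2), 15, 3),
    s3 = matrix(rnorm(15 * 3, -1), 15, 3))
  m <- trainClassifier(samples, regularization = 0)
  for (k in 1:3)
    expect_equal(unname(m@means[k, ]), colMeans(samples[[k]]))
  pooled <- Reduce(`+`, lapply(samples, function(s)
    (nrow(s) - 1) * stats::cov(s))) / (50 - 3)
  expect_equal(m@covariance, pooled)

  expect_error(trainClassifier(list(a = matrix(1:5))), "two classes")
  expect_error(trainClassifier(list(a = matrix(1:5), b = matrix(1))),
               "fewer than 2")
  # frequency priors
  mf <- trainClassifier(samples, priors = "frequency")
  expect_equal(mf@priors, c(20, 15, 15) / 50)
})

test_that("classification is nearest-mean at class centres with midpoint boundaries", {
  m <- trainClassifier(list(a = matrix(rnorm(50, 0, 1)),
                            b = matrix(rnorm(50, 2, 1))))
  # force the exact textbook setting: means 0 and 2, unit variance
  m@means[, 1] <- c(0, 2)
  m@covariance[1, 1] <- 1
  expect_equal(classifyPixels(matrix(c(0.999, 1.001, 0, 2)), m),
               c(1L, 2L, 1L, 2L))
  # exact tie at the midpoint goes to the lowest class code
  expect_equal(classifyPixels(matrix(1), m), 1L)

  # multivariate: a pixel exactly at a class mean gets that class
  set.seed(3)
  samples <- lapply(stats::setNames(1:5, paste0("c", 1:5)), function(k)
    matrix(rnorm(40 * 4, mean = k), 40, 4))
  mm <- trainClassifier(samples)
  expect_equal(classifyPixels(mm@means, mm), 1:5)
})

test_that("LDA argmax equals the brute-force Gaussian posterior on random pixels", {
  set.seed(42)
  samples <- lapply(stats::setNames(1:5, paste0("c", 1:5)), function(k)
    matrix(rnorm(60 * 4, mean = c(k, -k, k / 2, 0), sd = 1 + k / 5), 60, 4))
  model <- trainClassifier(samples)
  X <- matrix(rnorm(1000 * 4, 0, 3), 1000, 4)
  got <- classifyPixels(X, model)
  # oracle: full Gaussian log-posterior with the shared covariance
  Sinv <- solve(model@covariance)
  logdet <- determinant(model@covariance, logarithm = TRUE)$modulus
  post <- sapply(seq_len(5), function(k) {
    d <- sweep(X, 2, model@means[k, ])
    -0.5 * rowSums((d %*% Sinv) * d) - 0.5 * logdet +
      log(model@priors[k])
  })
  oracle <- apply(post, 1, which.max)
  expect_equal(got, as.integer(oracle))
})

test_that("classification is equivariant under feature translation and deterministic", {
  set.seed(8)
  samples <- lapply(stats::setNames(1:3, c("a", "b", "c")), function(k)
    matrix(rnorm(30 * 2, mean = k), 30, 2))
  shift <- c(5, -3)
  shifted <- lapply(samples, function(s) sweep(s, 2, shift, "+"))
  m1 <- trainClassifier(samples)
  m2 <- trainClassifier(shifted)
  X <- matrix(rnorm(200 * 2), 200, 2)
  expect_equal(classifyPixels(X, m1),
               classifyPixels(sweep(X, 2, shift, "+"), m2))
  expect_identical(classifyPixels(X, m1), classifyPixels(X, m1))
})

test_that("models serialize to JSON and round-trip identical predictions", {
  td <- withr::local_tempdir()
  set.seed(13)
  samples <- lapply(stats::setNames(1:4, paste0("s", 1:4)), function(k)
    matrix(rnorm(25 * 3, mean = k / 2), 25, 3))
  model <- trainClassifier(samples)
  f <- file.path(td, "model.json")
  writeClassifier(model, f)
  back <- readClassifier(f)
  expect_equal(back@means, model@means)
  expect_equal(back@covariance, model@covariance)
  expect_equal(back@priors, model@priors)
  probe <- matrix(rnorm(500 * 3), 500, 3)
  expect_identical(classifyPixels(probe, back),
                   classifyPixels(probe, model))
  expect_error(readClassifier(file.path(td, "missing.json")), "not found")
})

test_that("the pixel classifier trains from annotated images and separates the stains", {
  model <- testModel()
  expect_equal(model@classes, names(labelScheme()))
  expect_equal(model@channels, c("vessel", "macrophage", "tumor",
                                 "counterstain"))
  # on a noise-free slide, predicted labels match the ground-truth mask
  g <- generateSlide(smallSpec(2, seed = 31, noiseSd = 0))
  fs <- extractFeatures(g$image, defaultStainMatrix(), 1L)
  lab <- classifyPixels(fs, model)
  agree <- mean(lab == g$labelMask)
  expect_gt(agree, 0.99)

  # missing class in the annotation masks is an error
  img <- generateSlide(smallSpec(0, seed = 32))$image[1:50, 1:50, ,
                                                      drop = FALSE]
  mask <- matrix(labelScheme()[["STROMA"]], 50, 50)
  expect_error(trainPixelClassifier(img, mask), "missing class")
  # channel mismatch is an error
  expect_error(classifyPixels(matrix(rnorm(10), 5, 2), model),
               "channel mismatch")
})
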