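# Linear Bayesian pixel classification: Gaussian linear discriminant
# analysis with a shared (pooled) covariance, which is the standard model
# that is both "linear" (shared covariance implies linear boundaries) and
# "Bayesian" (posterior argmax with class priors).

#' Train a linear Bayesian (Gaussian LDA) classifier
#'
#' Computes per-class means, the pooled within-class covariance plus a
#' trace-scaled ridge, and class priors. Priors default to uniform because
#' pathologist-guided training sampling is not frequency-representative;
#' pass `priors = "frequency"` to use class frequencies, or a numeric
#' vector. The returned model is intended to be trained once, serialized,
#' and then applied frozen.
#'
#' @param samples named list of per-class numeric matrices (rows = samples,
#'   columns = features); at least two classes with >= 2 samples each.
#' @param regularization ridge coefficient; the pooled covariance gets
#'   `regularization * mean(diag(cov))` (or `regularization` itself when
#'   the pooled covariance is zero) added to its diagonal.
#' @param priors "uniform" (default), "frequency", or a numeric vector.
#' @param channels feature channel names (default from the sample columns).
#' @return a [ClassifierModel-class].
#' @export
trainClassifier <- function(samples, regularization = 1e-6,
                            priors = "uniform", channels = NULL) {
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list (one entry per class)")
  samples <- lapply(samples, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  K <- length(samples)
  if (K < 2) stop("need at least two classes")
  n <- vapply(samples, nrow, integer(1))
  if (any(n < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(samples)[n < 2], collapse = ", "))
  d <- unique(vapply(samples, ncol, integer(1)))
  if (length(d) != 1) stop("all classes must share the feature dimension")
  mv <- vapply(samples, colMeans, numeric(d))
  means <- if (d == 1) matrix(mv, ncol = 1) else t(mv)
  dimnames(means) <- NULL
  pooled <- matrix(0, d, d)
  for (k in seq_len(K)) {
    centered <- sweep(samples[[k]], 2, means[k, ])
    pooled <- pooled + crossprod(centered)
  }
  pooled <- pooled / (sum(n) - K)
  scale <- mean(diag(pooled))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  covReg <- pooled + diag(regularization * scale, d)
  pr <- if (identical(priors, "uniform")) rep(1 / K, K)
        else if (identical(priors, "frequency")) n / sum(n)
        else {
          if (length(priors) != K) stop("priors length must match classes")
          priors / sum(priors)
        }
  if (is.null(channels))
    channels <- colnames(samples[[1]]) %||% paste0("f", seq_len(d))
  methods::new("ClassifierModel",
               means = means, covariance = covReg, priors = as.numeric(pr),
               channels = channels, classes = names(samples),
               nPerClass = as.integer(n))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# linear discriminant scores: delta_k(x) = x' S^-1 mu_k
#   - 1/2 mu_k' S^-1 mu_k + log pi_k
#' @noRd
.ldaScores <- function(X, model) {
  Sinv <- solve(model@covariance)
  W <- Sinv %*% t(model@means)                       # d x K
  b <- -0.5 * colSums(t(model@means) * W) + log(model@priors)
  sweep(X %*% W, 2, b, "+")
}

#' Classify pixels (or feature vectors)
#'
#' Assigns every pixel the class with the highest linear discriminant
#' score; ties break to the lowest class code. Same stack and model always
#' give the identical label map.
#'
#' @param stack a [FeatureStack-class], or a numeric matrix of feature
#'   vectors (rows = observations).
#' @param model a [ClassifierModel-class] with matching channel count.
#' @return for a FeatureStack, an integer H x W label map with attribute
#'   `classes`; for a matrix, an integer vector of class codes.
#' @export
classifyPixels <- function(stack, model) {
  if (methods::is(stack, "FeatureStack")) {
    d <- dim(stack@data)
    if (d[3] != ncol(model@means))
      stop("channel mismatch: stack has ", d[3], ", model expects ",
           ncol(model@means))
    X <- matrix(stack@data, d[1] * d[2], d[3])
    lab <- matrix(.rowArgmaxCpp(.ldaScores(X, model)), d[1], d[2])
    attr(lab, "classes") <- model@classes
    lab
  } else {
    X <- as.matrix(stack)
    if (ncol(X) != ncol(model@means))
      stop("channel mismatch: input has ", ncol(X), ", model expects ",
           ncol(model@means))
    .rowArgmaxCpp(.ldaScores(X, model))
  }
}

#' Serialize / restore a classifier model
#'
#' The model file is JSON with named fields (schema version, channel and
#' class names, means, covariance, priors, per-class training counts); a
#' round trip reproduces identical predictions.
#'
#' @param model a [ClassifierModel-class].
#' @param path output/input JSON path.
#' @return `writeClassifier`: `path`, invisibly. `readClassifier`: a
#'   [ClassifierModel-class].
#' @export
writeClassifier <- function(model, path) {
  obj <- list(
    schema = "tmem-classifier-1",
    classes = model@classes,
    channels = model@channels,
    priors = model@priors,
    n_per_class = model@nPerClass,
    means = model@means,
    covariance = model@covariance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  if (!file.exists(path)) stop("classifier file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tmem-classifier-1"))
    stop("unrecognized classifier file schema")
  means <- matrix(as.numeric(obj$means), nrow = length(obj$classes),
                  byrow = FALSE)
  if (is.matrix(obj$means)) means <- obj$means
  cov <- obj$covariance
  if (!is.matrix(cov))
    cov <- matrix(as.numeric(cov), ncol(means), ncol(means))
  methods::new("ClassifierModel",
               means = means, covariance = cov,
               priors = as.numeric(obj$priors),
               channels = as.character(obj$channels),
               classes = as.character(obj$classes),
               nPerClass = as.integer(obj$n_per_class))
}

#' Train the five-class pixel classifier from annotated images
#'
#' Extracts stain feature channels from each training image, collects the
#' feature vectors of every annotated class from the paired label masks
#' (class codes per [labelScheme()]), deterministically subsamples up to
#' `nPerClass` pixels per class (evenly strided, no RNG), and trains the
#' shared-covariance LDA model.
#'
#' @param images list of RGB rasters (or a single raster).
#' @param labelMasks list of integer H x W masks with codes 1..5.
#' @param stains a [StainMatrix-class].
#' @param medianRadius median filter radius used for feature extraction.
#' @param nPerClass maximum training pixels per class (default 2000).
#' @param regularization passed to [trainClassifier()].
#' @return a [ClassifierModel-class] with the five classes of
#'   [labelScheme()].
#' @export
trainPixelClassifier <- function(images, labelMasks, stains = defaultStainMatrix(),
                                 medianRadius = 1L, nPerClass = 2000L,
                                 regularization = 1e-6) {
  if (!is.list(images)) images <- list(images)
  if (!is.list(labelMasks)) labelMasks <- list(labelMasks)
  stopifnot(length(images) == length(labelMasks))
  scheme <- labelScheme()
  pools <- stats::setNames(rep(list(NULL), length(scheme)), names(scheme))
  for (i in seq_along(images)) {
    fs <- extractFeatures(images[[i]], stains, medianRadius)
    d <- dim(fs@data)
    X <- matrix(fs@data, d[1] * d[2], d[3])
    lab <- as.integer(labelMasks[[i]])
    for (cls in names(scheme)) {
      idx <- which(lab == scheme[[cls]])
      if (length(idx))
        pools[[cls]] <- rbind(pools[[cls]], X[idx, , drop = FALSE])
    }
  }
  missing <- names(scheme)[vapply(pools, is.null, logical(1))]
  if (length(missing))
    stop("training data missing class(es): ", paste(missing, collapse = ", "))
  samples <- lapply(pools, function(P) {
    if (nrow(P) > nPerClass) {
      stride <- seq(1L, nrow(P), length.out = nPerClass)
      P <- P[unique(as.integer(round(stride))), , drop = FALSE]
    }
    P
  })
  trainClassifier(samples, regularization = regularization,
                  channels = colnames(stains@od))
}
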