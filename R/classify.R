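#' Build a feature matrix and labels from a flux dataset
#'
#' Internal fluxes become predictors after magnitude thresholding: every
#' flux with absolute value below `flux_zero_threshold` (default 1e-6) is
#' set to exactly zero, which stabilizes the LASSO fit. Labels depend on
#' the prediction mode: the carbon source, the nitrogen source, or the
#' joined `"carbon|nitrogen"` pair.
#'
#' @param dataset a `flux_dataset`.
#' @param mode one of `"joint"`, `"separate_C"`, `"separate_N"`.
#' @param flux_zero_threshold magnitude below which fluxes are zeroed.
#' @param restrict_to optional reaction ids to keep as predictors (e.g. the
#'   post-transport entry reactions); an error if none are present.
#' @return List with `x` (numeric matrix) and `y` (factor of labels).
#' @export
build_features <- function(dataset, mode = c("joint", "separate_C", "separate_N"),
                           flux_zero_threshold = 1e-6, restrict_to = NULL) {
  mode <- match.arg(mode)
  x <- dataset$X
  x[abs(x) < flux_zero_threshold] <- 0
  if (!is.null(restrict_to)) {
    keep <- intersect(colnames(x), restrict_to)
    if (!length(keep))
      stop("restrict_to shares no reaction with the dataset columns")
    x <- x[, keep, drop = FALSE]
  }
  y <- switch(mode,
              joint = paste(dataset$carbon, dataset$nitrogen, sep = "|"),
              separate_C = dataset$carbon,
              separate_N = dataset$nitrogen)
  list(x = x, y = factor(y))
}

#' Train an L1-regularized multinomial flux classifier
#'
#' Fits a multinomial logistic model with LASSO penalty (elastic-net mixing
#' fixed at alpha = 1) over a decreasing penalty path, and selects the
#' penalty `lambda` minimizing the cross-validated misclassification rate.
#' Fold assignment is stratified by class and is the only source of
#' randomness. Features are standardized internally before fitting.
#'
#' @param x feature matrix (observations x reactions).
#' @param y class labels (coerced to factor).
#' @param n_folds number of cross-validation folds (default 3).
#' @param lambda optional decreasing penalty path; by default the glmnet
#'   convention (up to 100 values log-spaced down from the smallest
#'   penalty that zeroes every coefficient).
#' @param seed integer seed for fold assignment.
#' @return An object of class `flux_classifier` with elements `classes`,
#'   `fit` (the glmnet path fit), `lambda`, `lambda_selected`,
#'   `cv_misclassification` (per-lambda curve), `feature_ids`, `n_folds`
#'   and `seed`.
#' @export
train_flux_classifier <- function(x, y, n_folds = 3, lambda = NULL, seed = 1L) {
  y <- factor(y)
  x <- as.matrix(x)
  if (nlevels(y) < 2L)
    stop("need at least 2 classes to train a classifier, got: ",
         paste(levels(y), collapse = ", "))
  counts <- table(y)
  if (any(counts == 0L))
    stop("class(es) absent from training data: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  loo <- n_folds >= length(y)
  if (loo) {
    n_folds <- length(y)
    if (any(counts < 2L))
      stop("leave-one-out CV needs at least 2 observations per class; too few for: ",
           paste(names(counts)[counts < 2L], collapse = ", "))
  } else if (any(counts < n_folds))
    stop("class(es) with fewer observations than cross-validation folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "))
  if (!is.null(lambda) && is.unsorted(rev(lambda), strictly = TRUE))
    stop("lambda path must be strictly decreasing")

  # entirely uninformative features (every column constant) admit only the
  # null model: zero coefficients, intercepts at the log class frequencies
  rng <- apply(x, 2L, function(col) max(col) - min(col))
  if (all(rng == 0)) {
    freq <- as.numeric(table(y)) / length(y)
    coefs <- lapply(levels(y), function(cl)
      stats::setNames(rep(0, ncol(x)), colnames(x)))
    names(coefs) <- levels(y)
    attr(coefs, "intercepts") <- stats::setNames(log(pmax(freq, 1e-12)),
                                                 levels(y))
    null_err <- mean(as.character(y) != levels(y)[which.max(freq)])
    return(structure(list(classes = levels(y), fit = NULL,
                          lambda = Inf, lambda_selected = Inf,
                          cv_misclassification = stats::setNames(null_err,
                                                                 "Inf"),
                          feature_ids = colnames(x), n_folds = n_folds,
                          seed = seed, stored_coefficients = coefs),
                     class = "flux_classifier"))
  }

  if (loo) {
    foldid <- seq_along(y)
  } else {
    foldid <- integer(length(y))
    with_seed(seed, for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    })
  }
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                        lambda = lambda, standardize = TRUE)
  path <- fit$lambda

  # explicit cross-validation loop: refit on each fold complement over the
  # same penalty path and score held-out hard labels with the package's own
  # argmax (ties broken by class order), so a tied null model scores as the
  # first class rather than as correct
  wrong <- matrix(NA, length(y), length(path))
  for (k in seq_len(n_folds)) {
    hold <- foldid == k
    fit_k <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                            family = "multinomial", alpha = 1,
                            lambda = path, standardize = TRUE)
    pred <- glmnet_class_matrix(fit_k, x[hold, , drop = FALSE], path,
                                levels(y))
    wrong[hold, ] <- pred != matrix(as.character(y)[hold], sum(hold),
                                    length(path))
  }
  cvm <- colMeans(wrong)
  # glmnet convention: the largest penalty attaining the minimum CV error
  lambda_selected <- max(path[cvm <= min(cvm) + 1e-12])

  structure(list(classes = levels(y),
                 fit = fit,
                 lambda = path,
                 lambda_selected = lambda_selected,
                 cv_misclassification = stats::setNames(cvm, format(path)),
                 feature_ids = colnames(x),
                 n_folds = n_folds, seed = seed),
            class = "flux_classifier")
}

# hard-label predictions of a multinomial glmnet fit at each penalty in
# `path`: argmax of linear scores, ties to the earlier class
glmnet_class_matrix <- function(fit, x, path, classes) {
  lk <- predict(fit, x, s = path, type = "link")
  out <- matrix(NA_character_, nrow(x), length(path))
  for (l in seq_along(path))
    out[, l] <- classes[apply(lk[, , l, drop = FALSE], 1L, which.max)]
  out
}

#' @export
print.flux_classifier <- function(x, ...) {
  nz <- length(unique(unlist(lapply(classifier_coefficients(x), function(b)
    names(b)[b != 0]))))
  cat("<flux_classifier> ", length(x$classes), " classes, ",
      length(x$feature_ids), " features\n", sep = "")
  cat("  lambda selected: ", format(x$lambda_selected),
      "  (", nz, " reactions with nonzero coefficients)\n", sep = "")
  invisible(x)
}

#' Per-class coefficient vectors at the selected penalty
#'
#' @param classifier a `flux_classifier`.
#' @param lambda penalty at which to extract coefficients (default: the
#'   cross-validation selection).
#' @return Named list (one element per class) of named numeric coefficient
#'   vectors over `feature_ids`; intercepts in attribute `"intercepts"`.
#' @export
classifier_coefficients <- function(classifier, lambda = classifier$lambda_selected) {
  if (!is.null(classifier$stored_coefficients)) {
    if (!isTRUE(all.equal(lambda, classifier$lambda_selected)))
      stop("a deserialized classifier only stores coefficients at its selected lambda")
    return(classifier$stored_coefficients)
  }
  cf <- stats::coef(classifier$fit, s = lambda, exact = FALSE)
  out <- lapply(cf, function(m) {
    v <- as.numeric(m)[-1]
    names(v) <- classifier$feature_ids
    v
  })
  attr(out, "intercepts") <- vapply(cf, function(m) as.numeric(m)[1], 0)
  out
}

#' Predict class labels from fluxes
#'
#' Hard labels by argmax of the per-class linear scores
#' `intercept + x %*% beta`; ties are broken in favour of the earlier class
#' in `classifier$classes` (alphabetical training order).
#'
#' @param object a `flux_classifier`.
#' @param newx feature matrix whose columns match `object$feature_ids`.
#' @param lambda penalty at which to predict (default: selected).
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.flux_classifier <- function(object, newx,
                                    lambda = object$lambda_selected, ...) {
  newx <- as.matrix(newx)
  if (is.null(colnames(newx)) ||
      !identical(colnames(newx), object$feature_ids))
    stop("feature columns of newx do not match the classifier's feature_ids")
  cf <- classifier_coefficients(object, lambda = lambda)
  icpt <- attr(cf, "intercepts")
  scores <- vapply(seq_along(object$classes),
                   function(k) icpt[k] + as.numeric(newx %*% cf[[k]]),
                   numeric(nrow(newx)))
  scores <- matrix(scores, nrow = nrow(newx))
  object$classes[apply(scores, 1L, which.max)]
}

#' Pair separate carbon and nitrogen predictions into joint labels
#'
#' A joint prediction is correct iff both components are correct.
#'
#' @param pred_C,pred_N equal-length label vectors.
#' @return Character vector of `"carbon|nitrogen"` labels.
#' @export
combine_separate <- function(pred_C, pred_N) {
  if (length(pred_C) != length(pred_N))
    stop("carbon and nitrogen prediction vectors differ in length (",
         length(pred_C), " vs ", length(pred_N), ")")
  paste(pred_C, pred_N, sep = "|")
}
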