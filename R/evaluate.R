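#' Misclassification rates and confusion matrices on a test set
#'
#' Scores either a pair of separately trained carbon/nitrogen classifiers
#' or a single joint classifier on a held-out flux dataset. The combined
#' (joint-axis) rate counts test observations with at least one wrong axis,
#' so overlapping carbon and nitrogen errors on the same observation count
#' once. Confusion matrices are normalized per actual class (each column of
#' actual labels sums to 1), the form the misclassification heat maps read.
#'
#' @param test a `flux_dataset` held out from training.
#' @param clf_C,clf_N separate-mode classifiers (mode `"separate_C"` /
#'   `"separate_N"`); supply both, or `clf_joint` instead.
#' @param clf_joint a joint-mode classifier over `"carbon|nitrogen"` labels.
#' @param flux_zero_threshold passed to [build_features()].
#' @param restrict_to passed to [build_features()].
#' @return An object of class `evaluation_report`: list with `mode`,
#'   `rates` (named fractions: `carbon`, `nitrogen`, `joint`), `errors`
#'   (misprediction counts per axis), `n_test`, and `confusion` (list of
#'   predicted-by-actual frequency matrices; each actual-class column sums
#'   to 1).
#' @export
score_classifiers <- function(test, clf_C = NULL, clf_N = NULL,
                              clf_joint = NULL, flux_zero_threshold = 1e-6,
                              restrict_to = NULL) {
  if (nrow(test$X) == 0L) stop("test dataset is empty")
  separate <- !is.null(clf_C) && !is.null(clf_N)
  if (!separate && is.null(clf_joint))
    stop("supply either clf_C and clf_N, or clf_joint")
  truth_C <- test$carbon; truth_N <- test$nitrogen
  if (separate) {
    fC <- build_features(test, "separate_C", flux_zero_threshold,
                         restrict_to = clf_C$feature_ids)
    fN <- build_features(test, "separate_N", flux_zero_threshold,
                         restrict_to = clf_N$feature_ids)
    pred_C <- predict(clf_C, fC$x)
    pred_N <- predict(clf_N, fN$x)
  } else {
    fj <- build_features(test, "joint", flux_zero_threshold,
                         restrict_to = clf_joint$feature_ids)
    pred_joint <- predict(clf_joint, fj$x)
    parts <- strsplit(pred_joint, "|", fixed = TRUE)
    pred_C <- vapply(parts, `[`, "", 1L)
    pred_N <- vapply(parts, `[`, "", 2L)
  }
  score_predictions(truth_C, truth_N, pred_C, pred_N,
                    mode = if (separate) "separate" else "joint")
}

#' Score label predictions against the truth
#'
#' @param truth_C,truth_N actual substrate labels.
#' @param pred_C,pred_N predicted labels, same length.
#' @param mode annotation recorded in the report.
#' @return An `evaluation_report`; see [score_classifiers()].
#' @export
score_predictions <- function(truth_C, truth_N, pred_C, pred_N,
                              mode = "separate") {
  n <- length(truth_C)
  stopifnot(length(truth_N) == n, length(pred_C) == n, length(pred_N) == n)
  wrong_C <- pred_C != truth_C
  wrong_N <- pred_N != truth_N
  wrong_joint <- wrong_C | wrong_N
  conf <- function(truth, pred) {
    classes <- sort(unique(c(truth, pred)))
    m <- table(factor(pred, classes), factor(truth, classes))
    out <- sweep(unclass(m), 2L, pmax(colSums(m), 1L), "/")
    names(dimnames(out)) <- NULL
    out
  }
  structure(list(mode = mode,
                 rates = c(carbon = mean(wrong_C), nitrogen = mean(wrong_N),
                           joint = mean(wrong_joint)),
                 errors = c(carbon = sum(wrong_C), nitrogen = sum(wrong_N),
                            joint = sum(wrong_joint)),
                 n_test = n,
                 confusion = list(carbon = conf(truth_C, pred_C),
                                  nitrogen = conf(truth_N, pred_N))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> mode:", x$mode, " n_test:", x$n_test, "\n")
  cat(sprintf("  misclassification  carbon %.2f%%  nitrogen %.2f%%  joint %.2f%%\n",
              100 * x$rates["carbon"], 100 * x$rates["nitrogen"],
              100 * x$rates["joint"]))
  invisible(x)
}

#' Expected misclassification rate of uniform random guessing
#'
#' @param n_classes number of equally likely classes (>= 1).
#' @return `1 - 1/n_classes` (0.98 for the 49 joint carbon/nitrogen pairs).
#' @export
random_guess_rate <- function(n_classes) {
  if (length(n_classes) != 1L || is.na(n_classes) || n_classes < 1)
    stop("n_classes must be a single integer >= 1")
  1 - 1 / n_classes
}

#' Predictive reactions of a trained classifier
#'
#' The reactions that actually drive prediction: those with a nonzero
#' coefficient for some class at the selected penalty.
#'
#' @param classifier a `flux_classifier`.
#' @return An object of class `predictive_reaction_set`: list with
#'   `per_class` (named list of reaction id vectors) and `all` (their
#'   union).
#' @export
predictive_reactions <- function(classifier) {
  cf <- classifier_coefficients(classifier)
  per_class <- lapply(cf, function(b) names(b)[b != 0])
  structure(list(per_class = per_class,
                 all = sort(unique(unlist(per_class, use.names = FALSE)))),
            class = "predictive_reaction_set")
}

#' @export
print.predictive_reaction_set <- function(x, ...) {
  cat("<predictive_reaction_set> ", length(x$all), " reactions across ",
      length(x$per_class), " classes\n", sep = "")
  invisible(x)
}

#' Union/intersection summary of two predictive-reaction sets
#'
#' @param set_C,set_N `predictive_reaction_set`s from the separate carbon
#'   and nitrogen models.
#' @return List with `n_C`, `n_N`, `n_shared`, `n_union`, and the id
#'   vectors `shared` and `union`.
#' @export
predictive_reaction_summary <- function(set_C, set_N) {
  shared <- intersect(set_C$all, set_N$all)
  uni <- union(set_C$all, set_N$all)
  list(n_C = length(set_C$all), n_N = length(set_N$all),
       n_shared = length(shared), n_union = length(uni),
       shared = shared, union = uni)
}

#' Train the separate carbon and nitrogen classifiers on one dataset
#'
#' @param train a `flux_dataset`.
#' @param n_folds,seed,flux_zero_threshold,restrict_to passed through to
#'   [build_features()] and [train_flux_classifier()].
#' @return List with `clf_C` and `clf_N`.
#' @export
train_separate_pair <- function(train, n_folds = 3, seed = 1L,
                                flux_zero_threshold = 1e-6,
                                restrict_to = NULL) {
  fC <- build_features(train, "separate_C", flux_zero_threshold, restrict_to)
  fN <- build_features(train, "separate_N", flux_zero_threshold, restrict_to)
  list(clf_C = train_flux_classifier(fC$x, fC$y, n_folds = n_folds, seed = seed),
       clf_N = train_flux_classifier(fN$x, fN$y, n_folds = n_folds, seed = seed))
}

#' Single-reaction ablation of the predictive set
#'
#' Removes one reaction at a time from the predictor set, retrains the
#' separate carbon and nitrogen models with the identical seed and penalty
#' selection procedure, and reports the change in combined (both-axes)
#' misclassification rate on the test set relative to the untouched
#' baseline. A delta of ~0 means prediction does not depend on that one
#' reaction.
#'
#' @param train,test `flux_dataset`s.
#' @param reaction_ids reactions to ablate (each must be a dataset column).
#' @param n_folds,seed,flux_zero_threshold training settings, held fixed
#'   across ablations so deltas reflect the feature removal only.
#' @return A data.frame with columns `reaction`, `rate` (combined rate
#'   without that reaction) and `delta` (rate - baseline rate); baseline in
#'   attribute `"baseline"`.
#' @export
ablation_study <- function(train, test, reaction_ids, n_folds = 3, seed = 1L,
                           flux_zero_threshold = 1e-6) {
  unknown <- setdiff(reaction_ids, colnames(train$X))
  if (length(unknown))
    stop("reaction id(s) not among dataset columns: ",
         paste(unknown, collapse = ", "))
  fit_rate <- function(keep) {
    pair <- train_separate_pair(train, n_folds, seed, flux_zero_threshold,
                                restrict_to = keep)
    rep <- score_classifiers(test, clf_C = pair$clf_C, clf_N = pair$clf_N,
                             flux_zero_threshold = flux_zero_threshold)
    unname(rep$rates["joint"])
  }
  all_ids <- colnames(train$X)
  baseline <- fit_rate(all_ids)
  rates <- vapply(reaction_ids,
                  function(id) fit_rate(setdiff(all_ids, id)), 0)
  structure(data.frame(reaction = reaction_ids, rate = rates,
                       delta = rates - baseline, row.names = NULL),
            baseline = baseline)
}

#' How an unseen substrate is predicted by trained classifiers
#'
#' Applies separately trained carbon and nitrogen classifiers to flux data
#' simulated with a substrate that was absent from training, and tabulates
#' which known class the novel substrate is predicted as, together with the
#' accuracy on the other (seen) axis.
#'
#' @param clf_C,clf_N trained separate-mode classifiers.
#' @param novel a `flux_dataset` whose `novel_axis` labels name a substrate
#'   unseen in training.
#' @param novel_axis `"carbon"` or `"nitrogen"`: the axis carrying the
#'   unseen substrate.
#' @param flux_zero_threshold passed to [build_features()].
#' @return List with `novel_axis`, `frequencies` (named fractions over the
#'   predicted known classes for the novel substrate), `top_prediction`,
#'   `seen_axis_accuracy` and `n`.
#' @export
novel_substrate_protocol <- function(clf_C, clf_N, novel,
                                     novel_axis = c("carbon", "nitrogen"),
                                     flux_zero_threshold = 1e-6) {
  novel_axis <- match.arg(novel_axis)
  fC <- build_features(novel, "separate_C", flux_zero_threshold,
                       restrict_to = clf_C$feature_ids)
  fN <- build_features(novel, "separate_N", flux_zero_threshold,
                       restrict_to = clf_N$feature_ids)
  pred_C <- predict(clf_C, fC$x)
  pred_N <- predict(clf_N, fN$x)
  if (novel_axis == "carbon") {
    pred_novel <- pred_C
    seen_acc <- mean(pred_N == novel$nitrogen)
  } else {
    pred_novel <- pred_N
    seen_acc <- mean(pred_C == novel$carbon)
  }
  freq <- sort(table(pred_novel) / length(pred_novel), decreasing = TRUE)
  list(novel_axis = novel_axis,
       frequencies = stats::setNames(as.numeric(freq), names(freq)),
       top_prediction = names(freq)[1],
       seen_axis_accuracy = seen_acc,
       n = length(pred_novel))
}

#' Select maximally distinct substrates by k-means on flux profiles
#'
#' Clusters one impurity-free flux profile per candidate substrate and
#' returns one representative per cluster (the profile closest to its
#' centroid), the procedure used to pick primary-source panels with
#' substantially distinct flux signatures.
#'
#' @param profiles numeric matrix, one row per candidate substrate (row
#'   names are substrate ids), columns are reactions.
#' @param k number of clusters / representatives (<= `nrow(profiles)`).
#' @param seed integer seed for the k-means initialization.
#' @param nstart random restarts for [stats::kmeans()].
#' @return Character vector of `k` selected substrate ids; the cluster
#'   assignment of every candidate in attribute `"cluster"`.
#' @export
select_distinct_substrates <- function(profiles, k, seed = 1L, nstart = 10) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("substrate", seq_len(nrow(profiles)))
  if (k > nrow(profiles))
    stop("k = ", k, " exceeds the ", nrow(profiles), " candidate profiles")
  if (k == nrow(profiles)) {
    out <- rownames(profiles)
    attr(out, "cluster") <- stats::setNames(seq_len(nrow(profiles)), out)
    return(out)
  }
  uniq <- unique(profiles)
  key <- apply(profiles, 1L, paste, collapse = "\r")
  ukey <- apply(uniq, 1L, paste, collapse = "\r")
  if (k >= nrow(uniq)) {
    # every distinct profile is its own cluster; duplicates share one
    ucl <- seq_len(nrow(uniq))
    centers <- uniq
    cluster <- ucl[match(key, ukey)]
  } else {
    km <- with_seed(seed, stats::kmeans(uniq, centers = k, nstart = nstart))
    centers <- km$centers
    cluster <- km$cluster[match(key, ukey)]
  }
  names(cluster) <- rownames(profiles)
  reps <- vapply(seq_len(max(cluster)), function(cl) {
    members <- which(cluster == cl)
    d <- rowSums(sweep(profiles[members, , drop = FALSE], 2L,
                       centers[cl, ], "-")^2)
    names(members)[which.min(d)]
  }, "")
  out <- reps
  attr(out, "cluster") <- cluster
  out
}
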