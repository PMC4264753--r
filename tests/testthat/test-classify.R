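test_that("flux magnitudes below the zero threshold become exact zeros", {
  toy <- toy_3x3()
  ds <- structure(list(X = matrix(c(5e-7, 2e-6, -5e-7, 0.5), 2, 2, byrow = TRUE,
                                  dimnames = list(NULL, c("r1", "r2"))),
                       carbon = c("cs1", "cs2"), nitrogen = c("ns1", "ns1"),
                       biomass = c(1, 1), replicate = 1:2,
                       impurities = list(NULL, NULL),
                       internal_ids = c("r1", "r2")),
                  class = "flux_dataset")
  f <- build_features(ds, "separate_C")
  expect_equal(unname(f$x[1, "r1"]), 0)
  expect_equal(unname(f$x[2, "r1"]), 0)   # -5e-7 also zeroed
  expect_equal(unname(f$x[1, "r2"]), 2e-6)
  # joint labels pair the axes
  fj <- build_features(ds, "joint")
  expect_equal(levels(fj$y), c("cs1|ns1", "cs2|ns1"))
  expect_error(build_features(ds, "joint", restrict_to = "absent"),
               "shares no reaction")
})

test_that("a single separable feature yields a sparse, perfect classifier", {
  d <- make_separable()
  clf <- quiet_glmnet(train_flux_classifier(d$x, d$y, n_folds = 3, seed = 1))
  expect_equal(min(clf$cv_misclassification), 0)
  expect_equal(unname(clf$cv_misclassification[match(clf$lambda_selected, clf$lambda)]), 0)
  nz <- unique(unlist(lapply(classifier_coefficients(clf),
                             function(b) names(b)[b != 0])))
  expect_identical(nz, "f")
  expect_identical(predict(clf, d$x), as.character(d$y))
})

test_that("at the largest penalty all coefficients vanish and the majority wins", {
  d <- make_separable()
  # unbalance the classes: drop a third of class B
  keep <- c(which(d$y == "A"), which(d$y == "B")[1:8])
  x <- d$x[keep, ]; y <- droplevels(d$y[keep])
  clf <- quiet_glmnet(train_flux_classifier(x, y, n_folds = 3, seed = 1))
  cf <- classifier_coefficients(clf, lambda = clf$lambda[1])
  expect_true(all(vapply(cf, function(b) all(b == 0), TRUE)))
  expect_true(all(predict(clf, x, lambda = clf$lambda[1]) == "A"))
  # an all-zero flux vector falls back to the largest intercept
  x0 <- matrix(0, 1, ncol(x), dimnames = list(NULL, colnames(x)))
  icpt <- attr(cf, "intercepts")
  expect_equal(predict(clf, x0, lambda = clf$lambda[1]),
               clf$classes[which.max(icpt)])
})

test_that("permuted labels drive test misclassification to the chance rate", {
  set.seed(11)
  k <- 4; n_per <- 18
  y <- factor(rep(paste0("class", 1:k), each = n_per))
  x <- matrix(stats::rnorm(k * n_per * 6), ncol = 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  x[, 1] <- as.integer(y)  # signal that permutation destroys
  half <- seq_len(k * n_per / 2)
  rates <- replicate(40, {
    # independent balanced null labelings for train and test, so the
    # held-out labels carry no information about the trained model
    y_tr <- sample(rep(levels(y), length.out = length(half)))
    y_te <- sample(rep(levels(y), length.out = length(half)))
    clf <- quiet_glmnet(train_flux_classifier(x[half, ], y_tr, n_folds = 3,
                                              seed = 1))
    mean(predict(clf, x[-half, ]) != y_te)
  })
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - (1 - 1 / k)), 3 * se + 0.02)
})

test_that("leave-one-out CV matches a brute-force hold-out loop", {
  set.seed(3)
  n <- 14
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- cbind(s = ifelse(y == "A", 1, -1) + stats::rnorm(n, 0, 0.4),
             n1 = stats::rnorm(n), n2 = stats::rnorm(n))
  clf <- quiet_glmnet(train_flux_classifier(x, y, n_folds = n, seed = 2))
  # independent oracle: refit without observation i, score it at each lambda
  errs <- matrix(NA, n, length(clf$lambda))
  for (i in seq_len(n)) {
    fit_i <- quiet_glmnet(glmnet::glmnet(x[-i, ], y[-i],
                                         family = "multinomial", alpha = 1,
                                         lambda = clf$lambda))
    cfs <- stats::coef(fit_i, s = clf$lambda)
    for (l in seq_along(clf$lambda)) {
      sc <- vapply(cfs, function(m) {
        mm <- as.matrix(m)
        mm[1, l] + sum(mm[-1, l] * x[i, ])
      }, 0)
      errs[i, l] <- levels(y)[which.max(sc)] != as.character(y[i])
    }
  }
  expect_equal(unname(clf$cv_misclassification), colMeans(errs))
})

test_that("coefficient support only grows as the penalty decreases", {
  d <- make_separable(n_per = 20, p_noise = 6)
  clf <- quiet_glmnet(train_flux_classifier(d$x, d$y, n_folds = 3, seed = 1))
  nnz <- function(l) {
    cf <- classifier_coefficients(clf, lambda = l)
    length(unique(unlist(lapply(cf, function(b) names(b)[b != 0]))))
  }
  idx <- unique(round(seq(1, length(clf$lambda), length.out = 5)))
  counts <- vapply(clf$lambda[idx], nnz, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("predictions are invariant to a constant shift of all intercepts", {
  d <- make_separable()
  clf <- quiet_glmnet(train_flux_classifier(d$x, d$y, n_folds = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(clf, path)
  lite <- read_classifier_json(path)
  shifted <- lite
  attr(shifted$stored_coefficients, "intercepts") <-
    attr(shifted$stored_coefficients, "intercepts") + 7.5
  expect_identical(predict(lite, d$x), predict(shifted, d$x))
  expect_identical(predict(lite, d$x), predict(clf, d$x))
})

test_that("separate predictions combine by the both-axes-correct rule", {
  expect_error(combine_separate(c("a", "b"), "x"), "differ in length")
  truth_C <- c("g", "g", "a", "a"); truth_N <- c("n", "m", "n", "m")
  pred_C <- c("g", "a", "a", "a")   # error on obs 2
  pred_N <- c("n", "m", "m", "m")   # error on obs 3
  joint <- combine_separate(pred_C, pred_N)
  expect_equal(joint[1], "g|n")
  rep <- score_predictions(truth_C, truth_N, pred_C, pred_N)
  # disjoint error sets: combined count is the sum
  expect_equal(unname(rep$errors["joint"]),
               unname(rep$errors["carbon"] + rep$errors["nitrogen"]))
  expect_equal(unname(rep$rates["joint"]), 0.5)
  # overlapping errors count observations, not axes
  rep2 <- score_predictions(truth_C, truth_N,
                            c("a", "g", "a", "a"), c("m", "m", "n", "m"))
  expect_equal(unname(rep2$errors["joint"]), 1)
})

test_that("degenerate training inputs are rejected with named classes", {
  d <- make_separable()
  expect_error(train_flux_classifier(d$x, rep("A", nrow(d$x))),
               "at least 2 classes")
  y3 <- as.character(d$y); y3[1] <- "C"
  expect_error(train_flux_classifier(d$x, factor(y3), n_folds = 3), "C")
  clf <- quiet_glmnet(train_flux_classifier(d$x, d$y, n_folds = 3, seed = 1))
  expect_error(predict(clf, d$x[, rev(colnames(d$x))]), "feature columns")
  expect_error(train_flux_classifier(d$x, d$y, lambda = c(0.1, 0.2)),
               "strictly decreasing")
})
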