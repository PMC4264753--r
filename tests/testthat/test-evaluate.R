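test_that("perfect and constant predictions score as expected", {
  k <- 4
  truth <- rep(paste0("s", 1:k), each = 5)
  rep_perfect <- score_predictions(truth, truth, truth, truth)
  expect_equal(unname(rep_perfect$rates), c(0, 0, 0))
  expect_equal(unname(diag(rep_perfect$confusion$carbon)), rep(1, k))
  # constant prediction on balanced classes: 1 - 1/k
  const <- rep("s1", length(truth))
  rep_const <- score_predictions(truth, truth, const, const)
  expect_equal(unname(rep_const$rates["carbon"]), 1 - 1 / k)
  # invariant to permuting observation order
  o <- sample(length(truth))
  rep_perm <- score_predictions(truth[o], truth[o], const[o], const[o])
  expect_equal(rep_perm$rates, rep_const$rates)
  expect_equal(rep_perm$confusion, rep_const$confusion)
  # confusion columns are per-actual-class frequencies
  expect_equal(unname(colSums(rep_const$confusion$carbon)), rep(1, k))
})

test_that("confusion matrices survive a CSV round-trip", {
  truth <- rep(c("a", "b", "c"), each = 4)
  pred <- c(truth[-1], "a")
  rep1 <- score_predictions(truth, truth, pred, truth)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep1$confusion$carbon, path)
  back <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  expect_equal(back, rep1$confusion$carbon, tolerance = 1e-12)
})

test_that("random guessing baseline is one minus one over k", {
  expect_equal(random_guess_rate(49), 48 / 49)
  expect_equal(round(100 * random_guess_rate(49)), 98)
  expect_equal(random_guess_rate(1), 0)
  expect_equal(random_guess_rate(2), 0.5)
  expect_error(random_guess_rate(0), ">= 1")
})

test_that("predictive sets obey shrinkage limits and set algebra", {
  d <- make_separable(n_per = 15, p_noise = 3)
  clf <- quiet_glmnet(train_flux_classifier(d$x, d$y, n_folds = 3, seed = 1))
  # at the all-zero end of the path nothing is predictive
  clf_null <- clf
  clf_null$lambda_selected <- clf$lambda[1]
  expect_length(predictive_reactions(clf_null)$all, 0)

  set.seed(2)
  d2 <- list(x = d$x[, c(2, 3, 4, 1)], y = d$y)
  clf2 <- quiet_glmnet(train_flux_classifier(d2$x, d2$y, n_folds = 3, seed = 1))
  s1 <- predictive_reactions(clf)
  s2 <- predictive_reactions(clf2)
  sm <- predictive_reaction_summary(s1, s2)
  expect_equal(sm$n_union, sm$n_C + sm$n_N - sm$n_shared)
})

test_that("ablation flags only the reaction that separates the classes", {
  train <- make_discriminating_dataset(seed = 4)
  test <- make_discriminating_dataset(seed = 5)
  res <- quiet_glmnet(ablation_study(train, test, c("disc", "noise"),
                                     seed = 1))
  expect_equal(attr(res, "baseline"), 0)
  # dropping the unused noise feature changes nothing
  expect_lt(abs(res$delta[res$reaction == "noise"]), 1e-3)
  # dropping the only carbon-discriminating reaction breaks carbon calls:
  # the generating process then makes cs1/cs2 indistinguishable (Bayes 0.5)
  expect_gt(res$delta[res$reaction == "disc"], 0.25)
  expect_error(ablation_study(train, test, "absent"), "absent")
})

test_that("a novel substrate maps onto its nearest known signature", {
  train <- make_discriminating_dataset(seed = 4)
  pair <- quiet_glmnet(train_separate_pair(train, seed = 1))
  novel <- make_discriminating_dataset(seed = 6)
  novel$carbon <- rep("cs_new", length(novel$carbon))  # flux signature = cs1
  novel$X[, "disc"] <- 10 + stats::rnorm(length(novel$carbon), 0, 0.1)
  out <- novel_substrate_protocol(pair$clf_C, pair$clf_N, novel,
                                  novel_axis = "carbon")
  expect_equal(out$top_prediction, "cs1")
  expect_equal(unname(out$frequencies["cs1"]), 1)
  expect_gt(out$seen_axis_accuracy, 0.95)
})

test_that("k-means substrate selection returns one representative per group", {
  prof <- rbind(g1a = c(10, 0, 0), g1b = c(10.1, 0, 0),
                g2a = c(0, 9, 0), g2b = c(0, 9.2, 0),
                g3a = c(0, 0, 7))
  sel <- select_distinct_substrates(prof, k = 3, seed = 1)
  expect_length(sel, 3)
  cl <- attr(sel, "cluster")
  expect_equal(cl[["g1a"]], cl[["g1b"]])
  expect_equal(cl[["g2a"]], cl[["g2b"]])
  expect_length(unique(cl[c("g1a", "g2a", "g3a")]), 3)
  # k equal to the number of profiles returns everything
  expect_setequal(select_distinct_substrates(prof, k = 5), rownames(prof))
  # exact duplicates always share a cluster
  prof2 <- rbind(prof, g3b = c(0, 0, 7))
  sel2 <- select_distinct_substrates(prof2, k = 5, seed = 1)
  cl2 <- attr(sel2, "cluster")
  expect_equal(cl2[["g3a"]], cl2[["g3b"]])
  expect_error(select_distinct_substrates(prof, k = 9), "exceeds")
})
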