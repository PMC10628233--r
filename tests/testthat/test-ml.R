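test_that("AUROC matches brute-force pair enumeration, including ties", {
  expect_equal(auroc(c(.9, .4, .4, .1), c(TRUE, TRUE, FALSE, FALSE),
                     ci = FALSE)$auroc, 0.875)
  expect_equal(auroc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                     ci = FALSE)$auroc, 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5), ci = FALSE)$auroc,
               0.5)
  brute <- function(s, l) {
    pairs <- expand.grid(i = which(l), j = which(!l))
    mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  }
  set.seed(2)
  for (r in 1:10) {
    n <- sample(6:50, 1)
    s <- round(stats::rnorm(n), 1)          # rounding forces ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(l) || !any(l)) next
    expect_equal(auroc(s, l, ci = FALSE)$auroc, brute(s, l))
  }
  ci <- auroc(c(.9, .8, .3, .2, .7, .1), rep(c(TRUE, FALSE), 3), seed = 5)
  expect_true(ci$ci_lower <= ci$auroc && ci$auroc <= ci$ci_upper)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("random forest wrapper is deterministic and separates separable data", {
  set.seed(3)
  X <- matrix(stats::rnorm(80 * 2), 80, 2)
  colnames(X) <- c("f1", "f2")
  y <- X[, 1] + X[, 2] > 0
  m1 <- train_rf(X, y, seed = 7, num_trees = 200)
  m2 <- train_rf(X, y, seed = 7, num_trees = 200)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_equal(auroc(predict(m1, X), y, ci = FALSE)$auroc, 1, tolerance = 0.01)
  expect_error(train_rf(X, rep(TRUE, 80)), "single-class")
  # label-permuted data gives chance-level CV performance
  set.seed(4)
  aucs <- vapply(1:3, function(s) {
    yp <- sample(y)
    folds <- ccia:::stratified_folds(yp, 5, seed = s)
    mean(vapply(1:5, function(f) {
      m <- train_rf(X[folds != f, ], yp[folds != f], seed = s, num_trees = 100)
      ccia:::.auc_rank(predict(m, X[folds == f, ]), yp[folds == f])
    }, 0))
  }, 0)
  expect_true(all(aucs > 0.25 & aucs < 0.75))
})

test_that("test samples never influence the trained model (leakage audit)", {
  sim <- tiny_sim(seed = 14)
  f <- log_transform(filter_features(sim$species))
  X <- t(f$values)
  y <- sim$metadata$status
  tr <- sim$metadata$cohort != "cohort03"
  m <- train_rf(X[tr, ], y[tr], seed = 1, num_trees = 100)
  p1 <- predict(m, X[!tr, ])
  # retraining with identical training data after shuffling the held-out
  # labels must reproduce the predictions bit for bit
  m2 <- train_rf(X[tr, ], y[tr], seed = 1, num_trees = 100)
  expect_identical(p1, predict(m2, X[!tr, ]))
})

test_that("LOOCV equals the pooled AUROC of the held-out scores", {
  set.seed(6)
  X <- matrix(stats::rnorm(20 * 3), 20, 3)
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("case", "control"), 10)
  X[, 1] <- X[, 1] + 2 * (y == "case")
  co <- rep("solo", 20)
  ev <- evaluate_within_cohort(X, y, co, scheme = "loocv", seed = 2,
                               num_trees = 100)
  expect_equal(nrow(ev$cells), 1L)
  sc <- vapply(1:20, function(j) {
    m <- train_rf(X[-j, ], y[-j], seed = 2 + j, num_trees = 100)
    predict(m, X[j, , drop = FALSE])
  }, 0)
  expect_equal(ev$cells$auroc, ccia:::.auc_rank(sc, y == "case"))
})

test_that("within-cohort CV separates a strong synthetic cohort", {
  sim <- tiny_sim(seed = 15, effect_size_log10 = 1.5)
  f <- log_transform(filter_features(sim$species))
  X <- t(f$values)
  keep <- sim$metadata$cohort == "cohort01"
  ev <- evaluate_within_cohort(X[keep, ], sim$metadata$status[keep],
                               sim$metadata$cohort[keep], scheme = "cv10",
                               n_repeats = 2, seed = 1, num_trees = 200)
  expect_gte(ev$cells$auroc, 0.8)
  expect_equal(ev$cells$n_repeats, 2L)
})

test_that("cohort-to-cohort produces a complete C x C matrix", {
  sim <- tiny_sim(seed = 16)
  f <- log_transform(filter_features(sim$species))
  X <- t(f$values)
  ev <- cohort_to_cohort(X, sim$metadata$status, sim$metadata$cohort,
                         seed = 1, n_repeats = 2, num_trees = 100)
  expect_equal(dim(ev$auroc_matrix), c(3L, 3L))
  expect_false(anyNA(ev$auroc_matrix))
  expect_true(all(ev$auroc_matrix >= 0 & ev$auroc_matrix <= 1))
  expect_error(cohort_to_cohort(X, sim$metadata$status,
                                rep("one", nrow(X)), seed = 1),
               "two cohorts")
})

test_that("LOCO yields one cell per held-out cohort with valid CIs", {
  sim <- tiny_sim(seed = 17)
  f <- log_transform(filter_features(sim$species))
  X <- t(f$values)
  ev <- leave_one_cohort_out(X, sim$metadata$status, sim$metadata$cohort,
                             seed = 1, num_trees = 100)
  expect_equal(nrow(ev$cells), 3L)
  expect_true(all(ev$cells$ci_lower <= ev$cells$auroc &
                    ev$cells$auroc <= ev$cells$ci_upper))
  expect_error(leave_one_cohort_out(X, sim$metadata$status,
                                    rep(c("a", "b"), length.out = nrow(X))),
               "3 cohorts")
})

test_that("FPR calibration hits its target on matched data and 0 at the boundary", {
  set.seed(9)
  X <- matrix(stats::rnorm(200 * 4), 200, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- X[, 1] > 0.5
  m <- train_rf(X, y, seed = 3, num_trees = 200)
  cal <- matrix(stats::rnorm(200 * 4), 200, 4, dimnames = list(NULL, colnames(X)))
  matched <- matrix(stats::rnorm(200 * 4), 200, 4,
                    dimnames = list(NULL, colnames(X)))
  rep_ <- specificity_fpr(m, cal, 0.10, list(matched = matched))
  expect_lt(abs(rep_$observed_fpr[["matched"]] - 0.10), 0.05)
  rep0 <- specificity_fpr(m, cal, 0, list(matched = cal))
  expect_equal(unname(rep0$observed_fpr[["matched"]]), 0)
  expect_error(specificity_fpr(m, cal, 0.1, list()), "no external")
})

test_that("panel combination inner-joins samples with namespace prefixes", {
  sp <- toy_matrix(matrix(1:6, 2), ids = c("A", "B"),
                   samples = c("s1", "s2", "s3"), state = "zscore")
  ko <- toy_matrix(matrix(1:4, 2), ids = c("K1", "K2"),
                   samples = c("s2", "s3"), namespace = "ko", state = "zscore")
  out <- combine_panels(sp, ko)
  expect_equal(dim(out), c(4L, 2L))
  expect_setequal(rownames(out), c("species|A", "species|B", "ko|K1", "ko|K2"))
  expect_equal(attr(out, "dropped_samples"), "s1")
  mb <- toy_matrix(matrix(1, 1), ids = "H1", samples = "s9",
                   namespace = "metabolite", state = "zscore")
  expect_error(combine_panels(sp, mb), "no samples")
})

test_that("IFE traces shrink strictly and recover planted informative features", {
  sim <- tiny_sim(seed = 18, effect_size_log10 = 1.5)
  f <- log_transform(filter_features(sim$species))
  X <- t(f$values)
  tt <- sim$truth$species
  planted <- intersect(tt$feature_id[tt$is_differential], colnames(X))
  tr <- iterative_feature_elimination(X, sim$metadata$status, cv_folds = 5,
                                      seed = 2, num_trees = 100)
  expect_true(all(diff(tr$iterations$feature_set_size) < 0))
  expect_equal(tr$iterations$feature_set_size[tr$best_iteration],
               length(tr$selected_features))
  expect_gte(sum(planted %in% tr$selected_features),
             ceiling(0.5 * length(planted)))
  # best iteration has maximal AUROC with smallest-set tie-break
  best_auc <- max(tr$iterations$mean_cv_auroc)
  at_best <- which(tr$iterations$mean_cv_auroc >= best_auc - 1e-12)
  expect_equal(tr$iterations$feature_set_size[tr$best_iteration],
               min(tr$iterations$feature_set_size[at_best]))
  # fewer than 3 features: trivial trace
  triv <- iterative_feature_elimination(X[, 1:2], sim$metadata$status)
  expect_identical(triv$selected_features, colnames(X)[1:2])
})
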