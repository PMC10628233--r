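#' Train a seed-controlled random-forest classifier
#'
#' Thin wrapper around \pkg{ranger} with the harness defaults: 500 trees,
#' sqrt(p) candidate features per split, class-balanced case weights, impurity
#' importance, single-threaded and fully determined by `seed`. Feature
#' standardization statistics (mean/SD) are learned from the training matrix
#' and frozen into the model, so downstream predictions on held-out samples
#' never leak test information into preprocessing.
#'
#' @param X samples x features numeric matrix (typically log-scale
#'   abundances; standardized internally).
#' @param y binary labels (`case`/`control`, factor, or logical TRUE = case).
#' @param num_trees,mtry forest size and per-split feature count.
#' @param seed integer seed.
#' @param standardize learn and apply per-feature z-scoring (default TRUE).
#' @return object of class `rf_model`; score samples with `predict()`, which
#'   returns the probability of `case`.
#' @export
train_rf <- function(X, y, num_trees = 500, mtry = NULL, seed = 1L,
                     standardize = TRUE) {
  X <- as.matrix(X)
  case <- .as_case_label(y)
  if (length(unique(case)) < 2L) stop("single-class y")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  center <- scl <- NULL
  Xs <- X
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[!is.finite(scl) | scl <= 0] <- 1
    Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  }
  yf <- factor(ifelse(case, "case", "control"), levels = c("control", "case"))
  w <- 1 / as.vector(table(yf)[yf])
  fit <- ranger::ranger(x = as.data.frame(Xs), y = yf,
                        num.trees = num_trees, mtry = min(mtry, ncol(X)),
                        probability = TRUE, importance = "impurity",
                        case.weights = w, seed = seed, num.threads = 1L)
  structure(list(model = fit, center = center, scale = scl,
                 feature_ids = colnames(X), seed = seed),
            class = "rf_model")
}

.as_case_label <- function(y) {
  if (is.logical(y)) return(y)
  s <- as.character(y)
  if (all(s %in% c("case", "control"))) return(s == "case")
  f <- factor(s)
  if (nlevels(f) != 2L) stop("y must be binary")
  f == levels(f)[2L]
}

#' @param object an `rf_model`.
#' @param newdata samples x features matrix with the training features.
#' @param ... unused.
#' @return probability of `case` per sample.
#' @rdname train_rf
#' @export
predict.rf_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$feature_ids, drop = FALSE]
  if (!is.null(object$center)) {
    Xn <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
  }
  stats::predict(object$model, data = as.data.frame(Xn),
                 num.threads = 1L)$predictions[, "case"]
}

#' Feature importance of a fitted rf_model
#' @param model an `rf_model`.
#' @return named numeric vector (impurity decrease).
#' @export
rf_importance <- function(model) model$model$variable.importance

#' Area under the ROC curve with bootstrap confidence interval
#'
#' Mann-Whitney formulation with half credit for tied scores; the 95% CI is a
#' stratified percentile bootstrap (cases and controls resampled separately).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary labels (TRUE/`case` = positive).
#' @param ci compute the bootstrap CI (default TRUE).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI coverage (default 0.95).
#' @return list with `auroc`, `ci_lower`, `ci_upper`.
#' @export
auroc <- function(scores, labels, ci = TRUE, n_boot = 1000, seed = 1L,
                  conf_level = 0.95) {
  case <- .as_case_label(labels)
  if (all(case) || !any(case)) stop("both classes required for AUROC")
  value <- .auc_rank(scores, case)
  lo <- hi <- NA_real_
  if (ci) {
    seed_state <- .seed_begin(seed)
    on.exit(.seed_end(seed_state), add = TRUE)
    i_case <- which(case); i_ctrl <- which(!case)
    boot <- vapply(seq_len(n_boot), function(b) {
      ic <- sample(i_case, replace = TRUE)
      in_ <- sample(i_ctrl, replace = TRUE)
      .auc_rank(c(scores[ic], scores[in_]),
                c(rep(TRUE, length(ic)), rep(FALSE, length(in_))))
    }, 0)
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  list(auroc = value, ci_lower = lo, ci_upper = hi)
}

.auc_rank <- function(scores, case) {
  r <- rank(scores)
  n1 <- sum(case); n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: shuffles within each class, then deals folds
# round-robin so every fold carries both classes whenever k <= min class size.
stratified_folds <- function(case, k, seed = NULL) {
  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  folds <- integer(length(case))
  for (cl in unique(case)) {
    i <- which(case == cl)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

#' Within-cohort cross-validated evaluation
#'
#' Per cohort, repeated stratified k-fold cross-validation (default 10-fold,
#' 5 repeats) of the random-forest classifier, reporting the mean and SD over
#' repeats of the fold-mean AUROC; or leave-one-out CV, where the pooled
#' held-out scores yield a single AUROC. Fold counts are reduced (with a
#' warning) for cohorts too small to support them.
#'
#' @param X samples x features matrix (log-scale; standardized inside each
#'   training split).
#' @param y binary labels aligned with rows of `X`.
#' @param cohorts cohort label per sample.
#' @param scheme `"cv10"` or `"loocv"`.
#' @param n_folds folds for `"cv10"` (default 10).
#' @param n_repeats CV repeats (default 5).
#' @param seed integer seed.
#' @param num_trees forest size.
#' @return an `EvalMatrix` (scheme plus a `cells` data.frame with one row per
#'   cohort: `train_unit`, `test_unit`, `auroc`, `sd`, `n_repeats`).
#' @export
evaluate_within_cohort <- function(X, y, cohorts, scheme = c("cv10", "loocv"),
                                   n_folds = 10, n_repeats = 5, seed = 1L,
                                   num_trees = 500) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  case <- .as_case_label(y)
  cohorts <- as.character(cohorts)
  cells <- NULL
  for (co in unique(cohorts)) {
    i <- which(cohorts == co)
    Xi <- X[i, , drop = FALSE]; ci <- case[i]
    if (scheme == "loocv") {
      sc <- numeric(length(i))
      for (j in seq_along(i)) {
        m <- train_rf(Xi[-j, , drop = FALSE], ci[-j], num_trees = num_trees,
                      seed = seed + j)
        sc[j] <- predict(m, Xi[j, , drop = FALSE])
      }
      a <- .auc_rank(sc, ci)
      cells <- rbind(cells, data.frame(train_unit = co, test_unit = co,
                                       auroc = a, sd = NA_real_,
                                       n_repeats = 1L))
    } else {
      k <- min(n_folds, min(sum(ci), sum(!ci)))
      if (k < n_folds) {
        warning("cohort ", co, ": fold count reduced to ", k)
      }
      if (k < 2L) stop("cohort ", co, " too small for cross-validation")
      reps <- vapply(seq_len(n_repeats), function(r) {
        folds <- stratified_folds(ci, k, seed = seed * 1000L + r)
        mean(vapply(seq_len(k), function(f) {
          tr <- folds != f
          m <- train_rf(Xi[tr, , drop = FALSE], ci[tr],
                        num_trees = num_trees, seed = seed * 1000L + r * 50L + f)
          .auc_rank(predict(m, Xi[!tr, , drop = FALSE]), ci[!tr])
        }, 0))
      }, 0)
      cells <- rbind(cells, data.frame(train_unit = co, test_unit = co,
                                       auroc = mean(reps), sd = stats::sd(reps),
                                       n_repeats = n_repeats))
    }
  }
  structure(list(scheme = scheme, cells = cells), class = "EvalMatrix")
}

#' Cohort-to-cohort transfer evaluation
#'
#' Trains one classifier per cohort (standardization statistics frozen from
#' the training cohort) and tests it on every other cohort; the diagonal
#' holds the within-cohort repeated 10-fold CV values.
#'
#' @inheritParams evaluate_within_cohort
#' @return an `EvalMatrix` with `auroc_matrix` (C x C, rows = training
#'   cohort) and `cells` (off-diagonal rows carry bootstrap CIs).
#' @export
cohort_to_cohort <- function(X, y, cohorts, seed = 1L, n_repeats = 5,
                             num_trees = 500) {
  X <- as.matrix(X)
  case <- .as_case_label(y)
  cohorts <- as.character(cohorts)
  cs <- unique(cohorts)
  if (length(cs) < 2L) stop("need at least two cohorts")
  M <- matrix(NA_real_, length(cs), length(cs), dimnames = list(cs, cs))
  within <- evaluate_within_cohort(X, case, cohorts, scheme = "cv10",
                                   n_repeats = n_repeats, seed = seed,
                                   num_trees = num_trees)
  cells <- within$cells
  diag(M) <- cells$auroc[match(cs, cells$train_unit)]
  for (a in cs) {
    ia <- cohorts == a
    m <- train_rf(X[ia, , drop = FALSE], case[ia], num_trees = num_trees,
                  seed = seed)
    for (b in setdiff(cs, a)) {
      ib <- cohorts == b
      sc <- predict(m, X[ib, , drop = FALSE])
      au <- auroc(sc, case[ib], seed = seed)
      M[a, b] <- au$auroc
      cells <- rbind(cells, data.frame(train_unit = a, test_unit = b,
                                       auroc = au$auroc, sd = NA_real_,
                                       n_repeats = 1L))
    }
  }
  structure(list(scheme = "cohort2cohort", auroc_matrix = M, cells = cells),
            class = "EvalMatrix")
}

#' Leave-one-cohort-out evaluation
#'
#' For each cohort, trains on all remaining cohorts pooled (standardization
#' learned on the pooled training data) and reports the AUROC on the held-out
#' cohort.
#'
#' @inheritParams evaluate_within_cohort
#' @return an `EvalMatrix` whose `cells` hold one row per held-out cohort.
#' @export
leave_one_cohort_out <- function(X, y, cohorts, seed = 1L, num_trees = 500) {
  X <- as.matrix(X)
  case <- .as_case_label(y)
  cohorts <- as.character(cohorts)
  cs <- unique(cohorts)
  if (length(cs) < 3L) stop("leave-one-cohort-out needs at least 3 cohorts")
  cells <- NULL
  models <- list()
  for (co in cs) {
    te <- cohorts == co
    m <- train_rf(X[!te, , drop = FALSE], case[!te], num_trees = num_trees,
                  seed = seed)
    sc <- predict(m, X[te, , drop = FALSE])
    au <- auroc(sc, case[te], seed = seed)
    cells <- rbind(cells, data.frame(train_unit = paste0("all_minus_", co),
                                     test_unit = co, auroc = au$auroc,
                                     ci_lower = au$ci_lower,
                                     ci_upper = au$ci_upper))
    models[[co]] <- m
  }
  structure(list(scheme = "loco", cells = cells, models = models),
            class = "EvalMatrix")
}

#' Calibrated false-positive-rate specificity check
#'
#' Chooses the score threshold as the (1 - target_fpr) quantile of the
#' calibration control scores, then reports the fraction of samples in each
#' external (non-target disease) set scoring above it — the cross-disease
#' false positive rate of the classifier.
#'
#' @param model fitted `rf_model`.
#' @param calibration_controls samples x features matrix of control samples.
#' @param target_fpr desired FPR on matched controls.
#' @param external_case_sets named list of samples x features matrices.
#' @return list of class `SpecificityReport`: `calibrated_threshold`,
#'   `target_fpr`, `observed_fpr` (named per external set).
#' @export
specificity_fpr <- function(model, calibration_controls, target_fpr,
                            external_case_sets) {
  if (!length(external_case_sets)) stop("no external sets supplied")
  if (any(vapply(external_case_sets, nrow, 0L) == 0L)) {
    stop("empty external set")
  }
  cal <- predict(model, calibration_controls)
  thr <- stats::quantile(cal, probs = 1 - target_fpr, names = FALSE)
  obs <- vapply(external_case_sets, function(Xe) {
    mean(predict(model, Xe) > thr)
  }, 0)
  structure(list(calibrated_threshold = thr, target_fpr = target_fpr,
                 observed_fpr = obs),
            class = "SpecificityReport")
}

#' Join standardized omics panels into one feature matrix
#'
#' Feature-wise concatenation with namespace-prefixed feature ids over the
#' inner join of sample ids; samples missing any layer are dropped (reported
#' in the `dropped_samples` attribute).
#'
#' @param ... `OmicsMatrix` objects (or a single named list of them).
#' @return numeric feature x sample matrix with ids like `species|<id>`.
#' @export
combine_panels <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && !inherits(mats[[1L]], "OmicsMatrix")) {
    mats <- mats[[1L]]
  }
  stopifnot(all(vapply(mats, inherits, TRUE, "OmicsMatrix")))
  ids <- lapply(mats, sample_ids)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no samples shared by all panels")
  dropped <- setdiff(unique(unlist(ids)), common)
  rows <- lapply(mats, function(m) {
    v <- m$values[, common, drop = FALSE]
    rownames(v) <- paste(m$namespace, rownames(v), sep = "|")
    v
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Iterative feature elimination driven by cross-validated importance
#'
#' Starting from a differential feature set, repeatedly: (1) evaluate the
#' mean stratified k-fold AUROC of the random forest on the current features,
#' (2) rank features by mean impurity importance across the fold models (so
#' held-out samples never influence the ranking), (3) drop the
#' lowest-importance fraction (default 10%, at least one feature), until
#' `min_features` remain. The selected set is the iteration with maximal mean
#' CV AUROC; ties resolve to the smallest set.
#'
#' @param X samples x features matrix (log-scale or z-scored).
#' @param y binary labels.
#' @param cv_folds folds per iteration (default 10, reduced for small data).
#' @param drop_fraction fraction of features removed per iteration.
#' @param seed integer seed.
#' @param num_trees forest size.
#' @param min_features stop once this few features remain (default 2).
#' @return list of class `IfeTrace`: `iterations` (data.frame with
#'   `feature_set_size`, `mean_cv_auroc`), `feature_sets` (list),
#'   `best_iteration`, `selected_features`.
#' @export
iterative_feature_elimination <- function(X, y, cv_folds = 10,
                                          drop_fraction = 0.1, seed = 1L,
                                          num_trees = 500, min_features = 2) {
  X <- as.matrix(X)
  case <- .as_case_label(y)
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 3L) {
    return(structure(list(
      iterations = data.frame(feature_set_size = ncol(X),
                              mean_cv_auroc = NA_real_),
      feature_sets = list(feats), best_iteration = 1L,
      selected_features = feats), class = "IfeTrace"))
  }
  k <- min(cv_folds, min(sum(case), sum(!case)))
  if (k < 2L) stop("too few samples per class for cross-validation")
  sizes <- integer(0); aucs <- numeric(0); sets <- list()
  current <- feats
  it <- 0L
  repeat {
    it <- it + 1L
    folds <- stratified_folds(case, k, seed = seed * 1000L + it)
    fold_auc <- numeric(k)
    imp <- matrix(0, length(current), k, dimnames = list(current, NULL))
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- train_rf(X[tr, current, drop = FALSE], case[tr],
                    num_trees = num_trees, seed = seed * 1000L + it * 50L + f)
      fold_auc[f] <- .auc_rank(predict(m, X[!tr, current, drop = FALSE]),
                               case[!tr])
      imp[, f] <- rf_importance(m)[current]
    }
    sizes <- c(sizes, length(current))
    aucs <- c(aucs, mean(fold_auc))
    sets[[it]] <- current
    if (length(current) <= min_features) break
    n_drop <- max(1L, floor(drop_fraction * length(current)))
    n_drop <- min(n_drop, length(current) - min_features)
    rank_imp <- rowMeans(imp)
    current <- current[order(rank_imp, decreasing = TRUE)]
    current <- current[seq_len(length(current) - n_drop)]
  }
  best_auc <- max(aucs)
  candidates <- which(aucs >= best_auc - 1e-12)
  best <- candidates[which.min(sizes[candidates])]
  structure(list(iterations = data.frame(feature_set_size = sizes,
                                         mean_cv_auroc = aucs),
                 feature_sets = sets,
                 best_iteration = best,
                 selected_features = sets[[best]]),
            class = "IfeTrace")
}
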