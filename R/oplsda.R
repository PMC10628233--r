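#' Fit an OPLS-DA model (one predictive + orthogonal components)
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome, NIPALS-style: the predictive weight vector is the
#' normalized covariance direction X'y; each orthogonal component captures
#' X-variation orthogonal to it (orthogonal-signal-correction filtering) and
#' is deflated from X before the single predictive component is extracted.
#' Features are centered and unit-variance scaled inside the model (idempotent
#' when the input is already z-scored) and the class labels are encoded 0/1
#' and centered.
#'
#' R2Y is the fitted fraction of label variance; Q2Y is the cross-validated
#' fraction 1 - PRESS/SS, with the entire pipeline (scaling, orthogonal
#' filtering, predictive fit) refit inside each of `cv_folds` folds.
#'
#' @param X samples x features numeric matrix.
#' @param y binary outcome: factor/character (`control` < `case`), logical, or
#'   0/1 numeric.
#' @param n_ortho number of orthogonal components (default 1).
#' @param cv_folds folds for Q2Y (default 7).
#' @param seed integer seed for fold assignment.
#' @return object of class `OplsModel`: scores `t`, weights `w`, loadings
#'   `p`, orthogonal blocks `t_ortho`, `w_ortho`, `p_ortho`, `R2Y`, `Q2Y`,
#'   `vip`, scaling statistics and fit metadata.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1, cv_folds = 7, seed = 1L) {
  X <- as.matrix(X)
  yv <- .as_binary_y(y)
  if (length(unique(yv)) < 2L) stop("constant y")
  n <- nrow(X)
  if (n != length(yv)) stop("X and y disagree on sample count")
  if (cv_folds < 2L || n <= cv_folds) stop("need n_samples > cv_folds >= 2")
  rk <- qr(scale(X))$rank
  if (n_ortho >= rk) stop("n_ortho must be smaller than rank(X)")

  fit <- .opls_fit(X, yv, n_ortho)
  ss_y <- sum((yv - mean(yv))^2)
  r2y <- 1 - sum((yv - fit$fitted)^2) / ss_y

  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  folds <- .random_folds(n, cv_folds)
  press <- 0
  for (f in seq_len(cv_folds)) {
    te <- folds == f
    m <- .opls_fit(X[!te, , drop = FALSE], yv[!te], n_ortho)
    pred <- .opls_predict(m, X[te, , drop = FALSE])
    press <- press + sum((yv[te] - pred)^2)
  }
  q2y <- 1 - press / ss_y

  p_feat <- ncol(X)
  vip <- sqrt(p_feat) * abs(fit$w)      # single predictive component
  names(vip) <- colnames(X)

  structure(list(t = fit$t, w = fit$w, p = fit$p, c = fit$c,
                 t_ortho = fit$To, w_ortho = fit$Wo, p_ortho = fit$Po,
                 n_ortho = fit$n_ortho,
                 center = fit$center, scale = fit$scale, y_mean = fit$y_mean,
                 R2Y = r2y, Q2Y = q2y, vip = vip,
                 cv_folds = cv_folds, seed = seed,
                 feature_ids = colnames(X)),
            class = "OplsModel")
}

.as_binary_y <- function(y) {
  if (is.factor(y) || is.character(y)) {
    s <- as.character(y)
    if (all(s %in% c("case", "control"))) return(as.numeric(s == "case"))
    f <- factor(s)
    if (nlevels(f) != 2L) stop("y must be binary")
    return(as.numeric(f) - 1)
  }
  if (is.logical(y)) return(as.numeric(y))
  u <- sort(unique(y))
  if (length(u) > 2L) stop("y must be binary")
  as.numeric(y == max(u))
}

.random_folds <- function(n, k) sample(rep_len(seq_len(k), n))

# Core O-PLS fit on raw X and 0/1 y. Scaling statistics are learned here so
# prediction can reuse them. Zero-variance columns get unit scale (their
# centered values are all zero and carry no weight).
.opls_fit <- function(X, yv, n_ortho) {
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  y_mean <- mean(yv)
  yc <- yv - y_mean

  w <- as.vector(crossprod(Xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw <= 0) stop("y is uncorrelated with every feature (zero weight vector)")
  w <- w / nw

  p_feat <- ncol(Xs)
  Wo <- Po <- matrix(0, p_feat, max(n_ortho, 0L))
  To <- matrix(0, nrow(Xs), max(n_ortho, 0L))
  Xd <- Xs
  kept <- 0L
  if (n_ortho > 0) {
    for (a in seq_len(n_ortho)) {
      t_ <- as.vector(Xd %*% w)
      p_ <- as.vector(crossprod(Xd, t_)) / sum(t_^2)
      wo <- p_ - sum(w * p_) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break                     # no orthogonal variation left
      wo <- wo / nwo
      to <- as.vector(Xd %*% wo)
      po <- as.vector(crossprod(Xd, to)) / sum(to^2)
      Xd <- Xd - tcrossprod(to, po)
      Wo[, a] <- wo; Po[, a] <- po; To[, a] <- to
      kept <- a
    }
  }
  t_ <- as.vector(Xd %*% w)
  p_ <- as.vector(crossprod(Xd, t_)) / sum(t_^2)
  c_ <- sum(yc * t_) / sum(t_^2)
  list(w = w, p = p_, t = t_, c = c_,
       Wo = Wo[, seq_len(kept), drop = FALSE],
       Po = Po[, seq_len(kept), drop = FALSE],
       To = To[, seq_len(kept), drop = FALSE],
       n_ortho = kept,
       center = center, scale = scl, y_mean = y_mean,
       fitted = t_ * c_ + y_mean)
}

.opls_predict <- function(fit, Xnew) {
  Xn <- sweep(sweep(as.matrix(Xnew), 2L, fit$center), 2L, fit$scale, "/")
  if (fit$n_ortho > 0) {
    for (a in seq_len(fit$n_ortho)) {
      to <- as.vector(Xn %*% fit$Wo[, a])
      Xn <- Xn - tcrossprod(to, fit$Po[, a])
    }
  }
  as.vector(Xn %*% fit$w) * fit$c + fit$y_mean
}

#' Predict class scores from an OPLS-DA model
#' @param object an `OplsModel`.
#' @param newdata samples x features matrix (same features as the fit).
#' @param ... unused.
#' @return numeric vector of predicted (continuous) class scores.
#' @export
predict.OplsModel <- function(object, newdata, ...) {
  .opls_predict(object, newdata)
}

#' VIP scores of an OPLS-DA model
#'
#' Variable importance in projection computed from the predictive
#' component(s) only (for the single predictive component of this model,
#' VIP_j = sqrt(p) |w_j| with the weight vector normalized, so
#' sum(VIP^2) = number of features). Features with VIP > 1 are conventionally
#' deemed influential.
#'
#' @param model an `OplsModel`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) model$vip

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the full pipeline on label-permuted data `n_perm` times and
#' compares the observed Q2Y with the permuted-label null:
#' perm_p = (1 + #\{Q2Y_perm >= Q2Y_obs\}) / (1 + n_perm). The study default
#' of 200 permutations gives a smallest attainable p of 1/201.
#'
#' @param X samples x features matrix.
#' @param y binary outcome.
#' @param n_perm number of label permutations (default 200).
#' @param seed integer seed.
#' @param n_ortho,cv_folds passed to [fit_oplsda()].
#' @return list with `q2y_obs`, `perm_null_q2y`, `perm_p`.
#' @export
permutation_validate <- function(X, y, n_perm = 200, seed = 1L,
                                 n_ortho = 1, cv_folds = 7) {
  if (n_perm < 20) warning("fewer than 20 permutations: poor p resolution")
  yv <- .as_binary_y(y)
  obs <- fit_oplsda(X, yv, n_ortho = n_ortho, cv_folds = cv_folds, seed = seed)
  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  null_q2 <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(yv)
    m <- try(fit_oplsda(X, yp, n_ortho = n_ortho, cv_folds = cv_folds,
                        seed = seed + i), silent = TRUE)
    if (inherits(m, "try-error")) return(-Inf)
    m$Q2Y
  }, 0)
  perm_p <- (1 + sum(null_q2 >= obs$Q2Y)) / (1 + n_perm)
  list(q2y_obs = obs$Q2Y, perm_null_q2y = null_q2, perm_p = perm_p)
}

#' Select candidate metabolites by FDR and VIP
#'
#' Intersection of the univariate rule (q below the FDR threshold, study
#' default 1e-4) with the multivariate rule (VIP > 1), both computed on the
#' same harmonized matrix.
#'
#' @param da_result `DAResult` on the metabolite namespace.
#' @param opls_model fitted `OplsModel` on the same features.
#' @param fdr_threshold q cutoff (default 1e-4).
#' @param vip_threshold VIP cutoff (default 1).
#' @return character vector of candidate feature ids (possibly empty).
#' @export
select_candidate_metabolites <- function(da_result, opls_model,
                                         fdr_threshold = 1e-4,
                                         vip_threshold = 1) {
  by_fdr <- da_result$feature_id[!is.na(da_result$q_fdr) &
                                   da_result$q_fdr < fdr_threshold]
  vip <- vip_scores(opls_model)
  by_vip <- names(vip)[vip > vip_threshold]
  intersect(by_fdr, by_vip)
}
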