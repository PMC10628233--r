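#' Per-sample alpha diversity (Shannon and Gini-Simpson)
#'
#' Shannon entropy (natural log) and the Gini-Simpson index (1 - sum p_i^2)
#' on per-sample renormalized relative abundances; computed through
#' \pkg{vegan}. The probability-of-identity form (sum p_i^2) is available via
#' `simpson_variant = "dominance"`.
#'
#' @param x raw `OmicsMatrix` (pre-log relative abundances).
#' @param simpson_variant `"gini"` (default, 1 - sum p^2) or `"dominance"`
#'   (sum p^2).
#' @return data.frame with columns `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(x, simpson_variant = c("gini", "dominance")) {
  simpson_variant <- match.arg(simpson_variant)
  v <- x$values
  cs <- colSums(v)
  if (any(cs == 0)) stop("all-zero sample(s): ",
                         paste(colnames(v)[cs == 0], collapse = ", "))
  p <- sweep(v, 2, cs, "/")
  sh <- vegan::diversity(t(p), index = "shannon")
  si <- vegan::diversity(t(p), index = "simpson")   # Gini-Simpson
  if (simpson_variant == "dominance") si <- 1 - si
  data.frame(sample_id = colnames(v), shannon = unname(sh),
             simpson = unname(si), row.names = NULL)
}

#' Compare alpha diversity between groups across cohorts
#'
#' Fits, per index, the linear model `index ~ status + cohort (+ covariates)`
#' with cohort as a fixed blocking effect, and reports the status-coefficient
#' p value, BH-adjusted across the tested indices. This is a deliberate
#' fixed-effect stand-in for covariate-adjusted meta-analytic alpha
#' comparisons.
#'
#' @param diversity output of [alpha_diversity()].
#' @param metadata `SampleMetadata`.
#' @param covariates optional extra metadata columns (e.g. age, gender).
#' @return data.frame with columns `index`, `estimate`, `p`, `q`.
#' @export
compare_alpha <- function(diversity, metadata, covariates = NULL) {
  md <- metadata[match(diversity$sample_id, metadata$sample_id), , drop = FALSE]
  if (length(unique(md$status)) < 2L) stop("need both status levels")
  idx_cols <- setdiff(names(diversity), "sample_id")
  res <- lapply(idx_cols, function(col) {
    df <- data.frame(y = diversity[[col]], status = md$status,
                     cohort = factor(md$cohort))
    rhs <- "status"
    if (length(unique(df$cohort)) > 1L) rhs <- c(rhs, "cohort")
    if (!is.null(covariates)) {
      for (cv in covariates) df[[cv]] <- md[[cv]]
      rhs <- c(rhs, covariates)
    }
    fit <- stats::lm(stats::reformulate(rhs, "y"), data = df)
    co <- summary(fit)$coefficients
    row <- grep("^status", rownames(co))[1L]
    data.frame(index = col, estimate = co[row, 1L], p = co[row, 4L])
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) on raw relative abundances;
#' computed through \pkg{vegan}. Bray-Curtis is a semimetric: symmetry and
#' range [0, 1] hold, the triangle inequality need not.
#'
#' @param x raw `OmicsMatrix`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  d <- vegan::vegdist(t(x$values), method = "bray")
  as.matrix(d)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA (Anderson's pseudo-F on the
#' Gower-centered distance matrix) via `vegan::adonis2`, with unrestricted
#' permutations and p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so the
#' smallest attainable p at 999 permutations is 0.001.
#'
#' @param dist square distance matrix (or `dist`) aligned with `labels`.
#' @param labels grouping vector.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class `PermanovaResult`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) != length(labels)) stop("labels do not match distance matrix")
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  df <- data.frame(g = labels)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g, data = df,
                        permutations = n_perm)
  structure(list(pseudo_F = fit$F[1L], R2 = fit$R2[1L],
                 p = fit$`Pr(>F)`[1L], n_permutations = n_perm),
            class = "PermanovaResult")
}

#' Principal coordinate analysis
#'
#' Classical (Torgerson) scaling of the double-centered distance matrix.
#' Negative eigenvalues, which arise for semimetrics like Bray-Curtis, are
#' clamped to zero; explained fractions are reported relative to the positive
#' inertia.
#'
#' @param dist square symmetric distance matrix or `dist`.
#' @param k number of axes to keep (default: all positive ones).
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `explained` (fractions of positive inertia).
#' @export
pcoa <- function(dist, k = NULL) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L,
                                         eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > 1e-12 * max(abs(eig)))
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- sc$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  eig_clamped <- pmax(eig, 0)
  list(coordinates = coords,
       eigenvalues = eig_clamped,
       explained = eig_clamped[seq_len(k)] / sum(eig_clamped))
}

#' Per-feature confounder variance partitioning
#'
#' For each feature, fits `abundance ~ status + confounder` on log-scale
#' abundances and reports the share of total variance attributed to each term
#' via type-II sums of squares (through `car::Anova`). In orthogonal designs
#' the two shares sum to at most 1. A confounder aliased with status yields
#' NA shares with a warning.
#'
#' @param x log-state `OmicsMatrix`.
#' @param metadata `SampleMetadata`.
#' @param confounder metadata column name.
#' @return data.frame of class `ConfounderPartition` with columns
#'   `feature_id`, `var_disease`, `var_confounder`, `confounder`.
#' @export
confounder_partition <- function(x, metadata, confounder) {
  if (!confounder %in% names(metadata)) {
    stop("unknown confounder column: ", confounder)
  }
  md <- metadata[match(sample_ids(x), metadata$sample_id), , drop = FALSE]
  conf <- md[[confounder]]
  if (!is.numeric(conf)) conf <- factor(conf)
  status <- md$status
  ok <- !is.na(conf) & !is.na(status)
  v <- x$values[, ok, drop = FALSE]
  conf <- conf[ok]; status <- droplevels(factor(status[ok]))
  res <- lapply(rownames(v), function(f) {
    df <- data.frame(y = v[f, ], status = status, conf = conf)
    fit <- stats::lm(y ~ status + conf, data = df)
    # aliased design (confounder collinear with status) leaves NA coefficients
    if (any(is.na(stats::coef(fit)))) {
      return(data.frame(feature_id = f, var_disease = NA_real_,
                        var_confounder = NA_real_))
    }
    aov2 <- car::Anova(fit, type = 2)
    ss <- aov2$`Sum Sq`
    terms_ <- rownames(aov2)
    ss_tot <- sum((df$y - mean(df$y))^2)
    data.frame(feature_id = f,
               var_disease = ss[match("status", terms_)] / ss_tot,
               var_confounder = ss[match("conf", terms_)] / ss_tot)
  })
  out <- do.call(rbind, res)
  if (all(is.na(out$var_disease))) {
    warning("confounder '", confounder,
            "' is aliased with status; shares reported as NA")
  }
  out$confounder <- confounder
  class(out) <- c("ConfounderPartition", "data.frame")
  out
}
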