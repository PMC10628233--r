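#' Cohort-blocked permutation Wilcoxon test
#'
#' Conditional rank test for a case/control difference with cohort as the
#' blocking factor. Within every block the samples are mid-ranked, the sum of
#' case ranks is centered at its conditional expectation, and the global
#' statistic Z = sum_b (S_b - E_b) / sqrt(sum_b V_b) uses the tie-corrected
#' conditional variance of each block (van Elteren form). The null
#' distribution is obtained by permuting status labels independently within
#' each block; when the total number of within-block case assignments is at
#' most `max_exact` the null is enumerated exhaustively instead. Two-sided
#' p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_perm) for the sampled null,
#' and the exact tail fraction for the enumerated one. A normal approximation
#' (`method = "normal"`) is available when permutation resolution is
#' insufficient, e.g. for very strict FDR thresholds.
#'
#' Blocks lacking either status contribute nothing; if no block carries both
#' statuses the test is undefined and errors.
#'
#' @param values numeric vector (log-scale abundances recommended).
#' @param status case/control labels (`"case"`/`"control"`, factor, or
#'   logical with TRUE = case).
#' @param cohort blocking factor; NULL means a single block.
#' @param n_perm permutations for the sampled null (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param method `"auto"` (exact when feasible, else permutation),
#'   `"exact"`, `"permutation"`, or `"normal"`.
#' @param max_exact largest number of within-block arrangements enumerated
#'   exhaustively (default 20000).
#' @return list with `p`, `statistic` (standardized Z), `method`, and for the
#'   exact path `n_arrangements`.
#' @export
blocked_wilcoxon <- function(values, status, cohort = NULL, n_perm = 10000,
                             seed = NULL,
                             method = c("auto", "exact", "permutation", "normal"),
                             max_exact = 20000) {
  method <- match.arg(method)
  case <- .as_case(status)
  if (is.null(cohort)) cohort <- rep("all", length(values))
  stopifnot(length(values) == length(case), length(case) == length(cohort))
  block <- factor(cohort)

  keep <- rep(FALSE, length(values))
  for (b in levels(block)) {
    i <- block == b
    if (any(case[i]) && any(!case[i])) keep[i] <- TRUE
  }
  if (!any(keep)) stop("no block contains both statuses")
  values <- values[keep]; case <- case[keep]
  block <- droplevels(block[keep])

  st <- .blocked_rank_summary(values, case, block)
  if (st$V <= 0) {
    return(list(p = 1, statistic = 0, method = "degenerate"))
  }
  z_obs <- (st$S - st$E) / sqrt(st$V)
  t_obs <- abs(st$S - st$E)
  eps <- 1e-9 * max(1, t_obs)

  n_arr <- prod(vapply(levels(block), function(b) {
    i <- block == b
    choose(sum(i), sum(case[i]))
  }, 0))
  if (method == "auto") {
    method <- if (n_arr <= max_exact) "exact" else "permutation"
  }

  if (method == "exact") {
    if (n_arr > max_exact) stop("exact enumeration infeasible (", n_arr,
                                " arrangements); use permutation")
    per_block <- lapply(levels(block), function(b) {
      i <- which(block == b)
      r <- rank(values[i])
      n1 <- sum(case[i])
      combos <- utils::combn(length(i), n1)
      colSums(matrix(r[combos], nrow = n1))
    })
    s_all <- Reduce(function(a, b) as.vector(outer(a, b, "+")), per_block)
    p <- mean(abs(s_all - st$E) >= t_obs - eps)
    return(list(p = p, statistic = z_obs, method = "exact",
                n_arrangements = n_arr))
  }

  if (method == "permutation") {
    seed_state <- .seed_begin(seed)
    on.exit(.seed_end(seed_state), add = TRUE)
    ranks <- numeric(length(values))
    for (b in levels(block)) {
      i <- block == b
      ranks[i] <- rank(values[i])
    }
    idx_by_block <- lapply(levels(block), function(b) which(block == b))
    n1_by_block <- vapply(idx_by_block, function(i) sum(case[i]), 0L)
    t_perm <- numeric(n_perm)
    for (j in seq_len(n_perm)) {
      s <- 0
      for (bi in seq_along(idx_by_block)) {
        i <- idx_by_block[[bi]]
        s <- s + sum(ranks[sample(i, n1_by_block[bi])])
      }
      t_perm[j] <- abs(s - st$E)
    }
    p <- (1 + sum(t_perm >= t_obs - eps)) / (1 + n_perm)
    return(list(p = p, statistic = z_obs, method = "permutation"))
  }

  # normal approximation with tie-corrected conditional variance
  p <- min(1, 2 * stats::pnorm(-abs(z_obs)))
  list(p = p, statistic = z_obs, method = "normal")
}

.as_case <- function(status) {
  if (is.logical(status)) return(status)
  s <- as.character(status)
  if (!all(s %in% c("case", "control"))) {
    stop("status must be 'case'/'control' (or logical)")
  }
  s == "case"
}

# Conditional moments of the within-block case rank sum with mid-ranks:
# E_b = n1_b (n_b + 1)/2; V_b = n1_b n2_b / (n_b (n_b - 1)) * sum (r - rbar)^2
.blocked_rank_summary <- function(values, case, block) {
  S <- E <- V <- 0
  for (b in levels(block)) {
    i <- block == b
    r <- rank(values[i])
    n <- length(r); n1 <- sum(case[i]); n2 <- n - n1
    S <- S + sum(r[case[i]])
    E <- E + n1 * (n + 1) / 2
    if (n > 1) V <- V + n1 * n2 / (n * (n - 1)) * sum((r - (n + 1) / 2)^2)
  }
  list(S = S, E = E, V = V)
}

# Vectorized blocked Wilcoxon over the rows of a feature x sample matrix.
# All features share one within-block permutation stream, which keeps the
# permutation path a single matrix product per dataset.
blocked_wilcoxon_matrix <- function(X, case, block, n_perm = 10000, seed = NULL,
                                    method = c("permutation", "normal")) {
  method <- match.arg(method)
  block <- droplevels(factor(block))
  keep <- rep(FALSE, ncol(X))
  for (b in levels(block)) {
    i <- block == b
    if (any(case[i]) && any(!case[i])) keep[i] <- TRUE
  }
  if (!any(keep)) stop("no block contains both statuses")
  X <- X[, keep, drop = FALSE]
  case <- case[keep]; block <- droplevels(block[keep])

  n_feat <- nrow(X); n_samp <- ncol(X)
  R <- matrix(0, n_feat, n_samp, dimnames = dimnames(X))
  E <- 0
  Vsum <- numeric(n_feat)
  for (b in levels(block)) {
    i <- which(block == b)
    n <- length(i); n1 <- sum(case[i]); n2 <- n - n1
    Rb <- t(apply(X[, i, drop = FALSE], 1L, rank))
    if (n_feat == 1L) Rb <- matrix(Rb, nrow = 1L)
    R[, i] <- Rb
    E <- E + n1 * (n + 1) / 2
    if (n > 1) {
      Vsum <- Vsum + n1 * n2 / (n * (n - 1)) * rowSums((Rb - (n + 1) / 2)^2)
    }
  }
  S <- as.vector(R %*% case)
  z <- ifelse(Vsum > 0, (S - E) / sqrt(Vsum), 0)

  if (method == "normal") {
    p <- pmin(1, 2 * stats::pnorm(-abs(z)))
    p[Vsum <= 0] <- 1
    return(list(p = p, statistic = z))
  }

  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  P <- matrix(0, n_samp, n_perm)
  for (b in levels(block)) {
    i <- which(block == b)
    n1 <- sum(case[i])
    for (j in seq_len(n_perm)) P[sample(i, n1), j] <- 1
  }
  t_obs <- abs(S - E)
  eps <- 1e-9 * pmax(1, t_obs)
  Tp <- abs(R %*% P - E)
  p <- (1 + rowSums(Tp >= (t_obs - eps))) / (1 + n_perm)
  p[Vsum <= 0] <- 1
  list(p = p, statistic = z)
}

#' Generalized fold change
#'
#' Robust location effect size: the mean over a quantile grid of the
#' difference between the case and control quantiles of (log-scale) values.
#' Positive values mean case-enriched. Default grid: 0.05 to 0.95 in steps
#' of 0.05.
#'
#' @param values numeric vector, log-transformed.
#' @param status case/control labels (see [blocked_wilcoxon()]).
#' @param quantile_grid probabilities at which quantiles are compared.
#' @return scalar gFC in the log units of `values`.
#' @export
generalized_fold_change <- function(values, status,
                                    quantile_grid = seq(0.05, 0.95, by = 0.05)) {
  case <- .as_case(status)
  if (all(case) || !any(case)) stop("both statuses required for gFC")
  qc <- stats::quantile(values[case], probs = quantile_grid, names = FALSE)
  qn <- stats::quantile(values[!case], probs = quantile_grid, names = FALSE)
  mean(qc - qn)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement; missing p values are propagated
#' as missing and excluded from the number of tests.
#'
#' @param p numeric vector of p values in [0, 1] (NA/NaN allowed).
#' @return q values, same length as `p`.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Cross-cohort differential abundance analysis
#'
#' Runs the cohort-blocked permutation Wilcoxon test and the generalized fold
#' change for every feature across all cohorts, adjusts p values by BH-FDR,
#' and computes per-cohort plain two-sided Wilcoxon p values and gFCs for the
#' per-cohort panels. Features with q below the threshold are flagged
#' significant. Cohorts lacking either status are excluded with a warning.
#'
#' @param x log-state `OmicsMatrix` (or plain matrix of log abundances).
#' @param metadata `SampleMetadata` covering the samples of `x`.
#' @param fdr_threshold significance threshold on q (study defaults: 1e-4 for
#'   species and metabolites, 1e-12 for KO genes).
#' @param n_perm permutations for the blocked test.
#' @param seed integer seed.
#' @param method `"permutation"` (default) or `"normal"` for the asymptotic
#'   approximation (needed when the claimed q is below permutation
#'   resolution).
#' @param quantile_grid gFC quantile grid.
#' @param per_cohort compute the per-cohort p/gFC panels (default TRUE).
#' @return data.frame of class `DAResult` with columns `feature_id`,
#'   `p_blocked`, `q_fdr`, `gfc`, `direction`, and per-cohort columns
#'   `p.<cohort>` / `gfc.<cohort>`; significant ids in attribute
#'   `significant`.
#' @export
run_ccia <- function(x, metadata, fdr_threshold = 0.05, n_perm = 10000,
                     seed = 1L, method = c("permutation", "normal"),
                     quantile_grid = seq(0.05, 0.95, by = 0.05),
                     per_cohort = TRUE) {
  method <- match.arg(method)
  X <- if (inherits(x, "OmicsMatrix")) x$values else x
  md <- metadata[match(colnames(X), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  case <- .as_case(md$status)
  block <- factor(md$cohort)
  usable <- vapply(levels(block), function(b) {
    i <- block == b
    any(case[i]) && any(!case[i])
  }, TRUE)
  if (!any(usable)) stop("no cohort contains both statuses")
  if (!all(usable)) {
    warning("cohort(s) without both statuses excluded: ",
            paste(levels(block)[!usable], collapse = ", "))
  }
  keep <- block %in% levels(block)[usable]
  X <- X[, keep, drop = FALSE]
  case <- case[keep]; block <- droplevels(block[keep])

  bw <- blocked_wilcoxon_matrix(X, case, block, n_perm = n_perm, seed = seed,
                                method = method)
  gfc <- apply(X, 1L, generalized_fold_change, status = case,
               quantile_grid = quantile_grid)
  res <- data.frame(feature_id = rownames(X),
                    p_blocked = bw$p,
                    q_fdr = bh_fdr(bw$p),
                    gfc = unname(gfc),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$direction <- ifelse(res$gfc > 0, "case_enriched",
                          ifelse(res$gfc < 0, "case_depleted", "none"))

  if (per_cohort) {
    for (b in levels(block)) {
      i <- block == b
      Xi <- X[, i, drop = FALSE]; ci <- case[i]
      res[[paste0("p.", b)]] <- apply(Xi, 1L, function(v) {
        stats::wilcox.test(v[ci], v[!ci], exact = FALSE,
                           correct = TRUE)$p.value
      })
      res[[paste0("gfc.", b)]] <- apply(Xi, 1L, generalized_fold_change,
                                        status = ci,
                                        quantile_grid = quantile_grid)
    }
  }
  attr(res, "significant") <-
    res$feature_id[!is.na(res$q_fdr) & res$q_fdr < fdr_threshold]
  attr(res, "fdr_threshold") <- fdr_threshold
  class(res) <- c("DAResult", "data.frame")
  res
}

#' Significant features of a DAResult
#' @param da a `DAResult`.
#' @return character vector of feature ids.
#' @export
significant_features <- function(da) attr(da, "significant", exact = TRUE)

#' KO pathway over-representation (hypergeometric) test
#'
#' One-sided hypergeometric upper-tail test per pathway with BH adjustment
#' across pathways. Pathway memberships are intersected with the tested
#' universe before counting. Typically run separately for case-enriched and
#' case-depleted query sets.
#'
#' @param query_kos character vector of significant KO ids.
#' @param pathway_map named list (pathway -> KO ids) or data.frame with
#'   columns `pathway`, `ko_id`.
#' @param universe all tested KO ids.
#' @return data.frame with columns `pathway`, `k_hits`, `K_pathway_size`,
#'   `n_query`, `N_universe`, `p_hyper`, `q_fdr`.
#' @export
ko_enrichment <- function(query_kos, pathway_map, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(query_kos)) stop("empty query set")
  if (is.data.frame(pathway_map)) {
    pathway_map <- split(pathway_map$ko_id, pathway_map$pathway)
  }
  query <- intersect(unique(query_kos), universe)
  N <- length(unique(universe))
  n <- length(query)
  res <- lapply(names(pathway_map), function(pw) {
    members <- intersect(unique(pathway_map[[pw]]), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k_hits = k, K_pathway_size = K,
               n_query = n, N_universe = N, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_fdr <- bh_fdr(out$p_hyper)
  out
}
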