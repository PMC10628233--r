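test_that("single-block exact enumeration matches the classical rank-sum test", {
  # cases {5,6,7} vs controls {1,2,3}: 2 of the C(6,3)=20 assignments are as
  # extreme as the observed split on either side
  r <- blocked_wilcoxon(c(5, 6, 7, 1, 2, 3),
                        rep(c("case", "control"), each = 3), method = "exact")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$n_arrangements, 20)

  # all 4v4 no-tie instances agree exactly with the exact rank-sum p
  combos <- utils::combn(8, 4)
  for (j in seq_len(ncol(combos))) {
    case <- seq_len(8) %in% combos[, j]
    p_ref <- stats::wilcox.test(seq_len(8)[case], seq_len(8)[!case],
                                exact = TRUE)$p.value
    p_ours <- blocked_wilcoxon(seq_len(8), case, method = "exact")$p
    expect_equal(p_ours, p_ref, tolerance = 1e-12)
  }
})

test_that("degenerate and blocked inputs are handled", {
  expect_equal(blocked_wilcoxon(rep(1, 8), rep(c("case", "control"), 4))$p, 1)
  expect_error(blocked_wilcoxon(1:4, rep("case", 4)), "no block")
  # a block lacking one status contributes nothing
  v <- c(5, 6, 7, 1, 2, 3, 9, 9)
  st <- c(rep(c("case", "control"), each = 3), "case", "case")
  bl <- c(rep("A", 6), "B", "B")
  r <- blocked_wilcoxon(v, st, bl, method = "exact")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  # permutation p respects the resolution bound
  set.seed(1)
  rp <- blocked_wilcoxon(stats::rnorm(40), rep(c("case", "control"), 20),
                         n_perm = 99, seed = 2, method = "permutation")
  expect_gte(rp$p, 1 / 100)
})

test_that("permutation, exact and normal paths agree where each is valid", {
  set.seed(7)
  v <- stats::rnorm(16)
  st <- rep(c("case", "control"), 8)
  bl <- rep(c("A", "B"), each = 8)
  pe <- blocked_wilcoxon(v, st, bl, method = "exact")$p
  pp <- blocked_wilcoxon(v, st, bl, method = "permutation", n_perm = 4999,
                         seed = 1)$p
  expect_equal(pp, pe, tolerance = 0.03)
  # asymptotic path approaches the sampled null at larger block sizes
  v2 <- stats::rnorm(120) + 0.4 * rep(c(1, 0), 60)
  st2 <- rep(c("case", "control"), 60)
  bl2 <- rep(c("A", "B"), each = 60)
  pn <- blocked_wilcoxon(v2, st2, bl2, method = "normal")$p
  pp2 <- blocked_wilcoxon(v2, st2, bl2, method = "permutation",
                          n_perm = 4999, seed = 1)$p
  expect_equal(pn, pp2, tolerance = 0.02)
})

test_that("gFC recovers pure location shifts and has the stated invariances", {
  set.seed(5)
  base <- stats::rnorm(50)
  st <- rep(c("case", "control"), each = 50)
  expect_equal(generalized_fold_change(c(base + 0.73, base), st), 0.73,
               tolerance = 1e-12)
  expect_equal(generalized_fold_change(c(base, base), st), 0, tolerance = 1e-12)
  # additive equivariance and sample-order invariance
  g1 <- generalized_fold_change(c(base + 0.5, base), st)
  ord <- sample(100)
  g2 <- generalized_fold_change(c(base + 0.5, base)[ord], st[ord])
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(generalized_fold_change(c(base + 0.5, base) + 2, st), g1,
               tolerance = 1e-12)
  expect_error(generalized_fold_change(base, rep("case", 50)), "both statuses")
})

test_that("BH adjustment matches the hand-computed example and handles NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  q <- bh_fdr(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.01, 0.02)))   # NA excluded from m
})

test_that("run_ccia flags planted features with correct directions", {
  sim <- tiny_sim(seed = 8, effect_size_log10 = 1.5)
  f <- log_transform(filter_features(sim$species))
  da <- run_ccia(f, sim$metadata, fdr_threshold = 0.05, n_perm = 999, seed = 1)
  expect_s3_class(da, "DAResult")
  expect_true(all(da$q_fdr >= da$p_blocked - 1e-12))
  expect_true(all(sign(da$gfc[da$direction == "case_enriched"]) == 1))
  # per-cohort panels exist for every cohort
  expect_true(all(paste0("p.", unique(sim$metadata$cohort)) %in% names(da)))
  tt <- sim$truth$species
  planted <- tt$feature_id[tt$is_differential]
  hit <- intersect(significant_features(da), planted)
  expect_gte(length(hit), ceiling(0.5 * length(planted)))
  dir_match <- merge(da[da$feature_id %in% hit, c("feature_id", "direction")],
                     tt, by = "feature_id")
  expect_true(all(dir_match$direction.x == dir_match$direction.y))
})

test_that("significance is invariant to sample and cohort ordering", {
  sim <- tiny_sim(seed = 12)
  f <- log_transform(filter_features(sim$species))
  da <- run_ccia(f, sim$metadata, fdr_threshold = 0.05, method = "normal",
                 per_cohort = FALSE)
  ord <- rev(seq_along(sample_ids(f)))
  f2 <- f
  f2$values <- f$values[, ord]
  da2 <- run_ccia(f2, sim$metadata, fdr_threshold = 0.05, method = "normal",
                  per_cohort = FALSE)
  expect_setequal(significant_features(da), significant_features(da2))
  expect_equal(da$p_blocked, da2$p_blocked, tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches combinatorial hand computations", {
  uni <- paste0("K", 1:10)
  pw <- list(pathA = paste0("K", 1:5), pathB = paste0("K", 6:10))
  full <- ko_enrichment(paste0("K", 1:5), pw, uni)
  expect_equal(full$p_hyper[full$pathway == "pathA"], 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(full$p_hyper[full$pathway == "pathB"], 1)   # zero hits
  all_q <- ko_enrichment(uni, pw, uni)
  expect_true(all(all_q$p_hyper == 1))                     # query = universe
  expect_error(ko_enrichment(character(0), pw, uni), "empty query")
  expect_error(ko_enrichment("K1", pw, character(0)), "empty universe")
})
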