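test_that("metabolite-KO linking equals a brute-force scan over all triples", {
  rt <- toy_reactions()
  links <- link_metabolites_to_kos(c("M1", "M6"), rt)
  expect_setequal(unique(links$ko_id), c("K1", "K2"))
  # brute force over every (row, compound) membership
  brute <- unique(unlist(lapply(seq_len(nrow(rt)), function(i) {
    comp <- union(rt$substrates[[i]], rt$products[[i]])
    if (length(intersect(comp, c("M1", "M6")))) rt$ko_id[i] else NULL
  })))
  expect_setequal(unique(links$ko_id), brute)
  # absent metabolite contributes nothing but is reported
  l2 <- link_metabolites_to_kos(c("M1", "ZZZ"), rt)
  expect_setequal(unique(l2$ko_id), c("K1", "K2"))
  expect_equal(attr(l2, "unlinked"), "ZZZ")
  l0 <- link_metabolites_to_kos(character(0), rt)
  expect_equal(nrow(l0), 0L)
})

make_ko_da <- function(sig, all = c("K1", "K2", "K3", "K4", "K5")) {
  structure(data.frame(
    feature_id = all,
    p_blocked = ifelse(all %in% sig, 1e-8, 0.5),
    q_fdr = ifelse(all %in% sig, 1e-6, 0.8),
    gfc = ifelse(all %in% sig, 1.2, 0.01),
    direction = ifelse(all %in% sig, "case_enriched", "none"),
    stringsAsFactors = FALSE), class = c("DAResult", "data.frame"),
    fdr_threshold = 0.05, significant = sig)
}

test_that("intersection with differential KOs is exact set algebra", {
  ko_da <- make_ko_da(c("K2", "K5"))
  hit <- intersect_with_differential(c("K1", "K2", "K3"), ko_da)
  expect_equal(hit$ko_id, "K2")
  expect_equal(hit$direction, "case_enriched")
  none <- intersect_with_differential(c("K4"), ko_da)
  expect_equal(nrow(none), 0L)
  expect_setequal(
    intersect_with_differential(c("K2", "K5"), ko_da)$ko_id,
    intersect(c("K2", "K5"), c("K2", "K5")))
})

test_that("top contributors match hand arithmetic and brute-force ordering", {
  strat <- stratified_ko_matrix(data.frame(
    ko_id = "K1",
    contributor = rep(c("spA", "spB"), 2),
    sample_id = rep(c("s1", "s2"), each = 2),
    abundance = c(0.75, 0.25, 0.075, 0.025)))
  kom <- toy_matrix(matrix(c(1, 0.1), 1), ids = "K1", samples = c("s1", "s2"),
                    namespace = "ko")
  tc <- top_contributors("K1", strat, kom)
  expect_equal(tc$contributor, c("spA", "spB"))
  expect_equal(tc$mean_fraction, c(0.75, 0.25), tolerance = 1e-12)
  expect_true(all(diff(tc$mean_fraction) <= 0))

  # 7 contributors: exactly 5 returned, order matches a brute-force sort;
  # the unclassified bucket is reported but does not count toward k
  set.seed(13)
  fracs <- c(stats::runif(7), 0.05)
  fracs <- fracs / sum(fracs)
  contr <- c(paste0("sp", 1:7), "unclassified")
  strat7 <- stratified_ko_matrix(data.frame(
    ko_id = "K9", contributor = contr, sample_id = "s1", abundance = fracs))
  kom7 <- toy_matrix(matrix(1, 1), ids = "K9", samples = "s1",
                     namespace = "ko")
  t7 <- top_contributors("K9", strat7, kom7, k = 5)
  expect_equal(nrow(t7), 5L)
  ref <- setdiff(contr[order(fracs, decreasing = TRUE)], "unclassified")[1:5]
  expect_equal(t7$contributor, ref)
  expect_equal(attr(t7, "unclassified_fraction"), fracs[8], tolerance = 1e-12)
  expect_lte(sum(t7$mean_fraction) + attr(t7, "unclassified_fraction"),
             1 + 1e-6)
  expect_error(top_contributors("K404", strat7, kom7), "K404")
})

test_that("MOBC assembly is pure, monotone in the differential set, and flags statuses", {
  rt <- toy_reactions()
  ko_da <- make_ko_da(c("K1", "K3"))
  mb_da <- structure(data.frame(
    feature_id = c("M1", "M2", "M6"),
    p_blocked = c(1e-9, 0.4, 1e-9),
    q_fdr = c(1e-7, 0.6, 1e-7),
    gfc = c(2, 0.1, -1),
    direction = c("case_enriched", "none", "case_depleted"),
    stringsAsFactors = FALSE), class = c("DAResult", "data.frame"),
    fdr_threshold = 1e-4)
  cands <- c("M1", "M6")
  links <- link_metabolites_to_kos(cands, rt)
  hits <- intersect_with_differential(links, ko_da)
  expect_setequal(hits$ko_id, "K1")
  map <- suppressWarnings(assemble_mobc_map(hits, links, rt, mb_da))
  expect_equal(length(map), 2L)            # K1 links through R1 and R2
  e1 <- map[[1]]
  expect_equal(e1$ko_id, "K1")
  # substrate M1 is significant and enriched; product M2 measured, not sig
  expect_equal(e1$substrates$status[e1$substrates$compound == "M1"],
               "case_enriched")
  expect_equal(e1$products$status[e1$products$compound == "M2"], "none")
  expect_true(e1$validated_in_both)
  # M3 is never measured
  r3_entry <- map[[2]]
  expect_equal(r3_entry$products$status[r3_entry$products$compound == "M6"],
               "case_depleted")
  # purity: identical inputs give identical exports
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  suppressWarnings({
    export_mobc_map(assemble_mobc_map(hits, links, rt, mb_da), tsv_path = f1)
    export_mobc_map(assemble_mobc_map(hits, links, rt, mb_da), tsv_path = f2)
  })
  expect_identical(readLines(f1), readLines(f2))
  # removing the KO from the differential set removes its entries
  map0 <- suppressWarnings(assemble_mobc_map(
    intersect_with_differential(links, make_ko_da(character(0))),
    links, rt, mb_da))
  expect_equal(length(map0), 0L)
  # every entry's KO is in both the linked set and the differential set
  for (e in map) {
    expect_true(e$ko_id %in% links$ko_id)
    expect_true(e$ko_id %in% significant_features(ko_da))
  }
})

test_that("end-to-end simulated MOBC recovers planted KO-metabolite couplings", {
  sim <- simulate_cohort_set(simulation_config(
    n_cohorts = 3, cases_per_cohort = 20, controls_per_cohort = 10,
    n_species = 80, n_ko = 40, n_metabolites = 20,
    n_differential = c(species = 10, ko = 6, metabolite = 5),
    metabolite_coupling_strength = 2.0, seed = 31))
  # reaction fixture wiring each metabolite to its truly coupled KOs
  coup <- sim$truth$metabolite_coupled_kos
  rt <- reaction_table(data.frame(
    ko_id = unlist(coup),
    reaction_id = paste0("R", seq_along(unlist(coup))),
    substrates = rep(names(coup), lengths(coup)),
    products = "HMDB_SINK",
    stringsAsFactors = FALSE))
  ko_da <- run_ccia(log_transform(filter_features(sim$ko)), sim$metadata,
                    fdr_threshold = 0.05, n_perm = 499, seed = 1,
                    per_cohort = FALSE)
  mb_da <- run_ccia(log_transform(filter_features(sim$metabolite)),
                    sim$metadata, fdr_threshold = 0.05, n_perm = 499,
                    seed = 1, per_cohort = FALSE)
  cands <- significant_features(mb_da)
  links <- link_metabolites_to_kos(cands, rt)
  hits <- intersect_with_differential(links, ko_da)
  truly <- sim$truth$ko$feature_id[sim$truth$ko$is_differential]
  expect_gte(sum(hits$ko_id %in% truly) / max(1, length(hits$ko_id)), 0.8)
  map <- assemble_mobc_map(hits, links, rt, mb_da,
                           stratified = sim$stratified, ko_matrix = sim$ko)
  for (e in map) {
    expect_true(all(e$top_contributors$mean_fraction >= 0))
    expect_true(all(diff(e$top_contributors$mean_fraction) <= 1e-12))
    expect_lte(nrow(e$top_contributors), 5L)
  }
})
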