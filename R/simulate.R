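#' Simulation configuration for multi-cohort coupled omics data
#'
#' Defines the generating model for a multi-cohort case-control study with
#' coupled species / KO / metabolite layers. Species log10 abundances are
#' log-normal with per-(cohort, feature) batch offsets and a planted
#' case/control location shift for differential features; KO abundances are
#' gene-content-weighted sums of species abundances (yielding a consistent
#' species-stratified store); metabolite log2 levels couple to the z-scored
#' abundance of their KO partners plus noise.
#'
#' Defaults emulate the structure of multi-cohort gut metagenome studies:
#' three cohorts, two cases per control within each cohort, heavy-tailed
#' species abundances, cohort batch offsets of similar magnitude to the
#' biological noise, and moderate zero inflation from detection limits.
#'
#' @param n_cohorts number of cohorts.
#' @param cases_per_cohort,controls_per_cohort integer vectors (recycled to
#'   `n_cohorts`) of per-cohort case and control counts; the default honours a
#'   1:2 control:case ratio.
#' @param n_species,n_ko,n_metabolites layer sizes.
#' @param n_differential named or unnamed vector of planted differential
#'   feature counts for species, KO and metabolites.
#' @param effect_size_log10 location shift (log10 units) applied to planted
#'   species in cases; its sign per feature is the planted direction.
#' @param batch_sd_log10 SD of the per-(cohort, feature) log10 offset.
#' @param zero_inflation_prob probability a species observation is below the
#'   detection limit (set to zero before renormalization).
#' @param gene_content_density expected fraction of species carrying a KO.
#' @param metabolite_coupling_strength slope linking a metabolite's log2 level
#'   to the mean z-scored log10 abundance of its coupled KOs.
#' @param noise_sd residual SD of metabolite log2 levels.
#' @param prob_enriched probability a planted feature is case-enriched (the
#'   remainder are case-depleted).
#' @param seed integer; fully determines the simulated data.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cohorts = 3,
                              cases_per_cohort = 40,
                              controls_per_cohort = 20,
                              n_species = 200,
                              n_ko = 150,
                              n_metabolites = 60,
                              n_differential = c(species = 20, ko = 15, metabolite = 10),
                              effect_size_log10 = 1.0,
                              batch_sd_log10 = 0.5,
                              zero_inflation_prob = 0.1,
                              gene_content_density = 0.05,
                              metabolite_coupling_strength = 1.0,
                              noise_sd = 0.5,
                              prob_enriched = 0.15,
                              seed = 1L) {
  cases_per_cohort <- rep_len(as.integer(cases_per_cohort), n_cohorts)
  controls_per_cohort <- rep_len(as.integer(controls_per_cohort), n_cohorts)
  nd <- n_differential
  if (is.null(names(nd))) names(nd) <- c("species", "ko", "metabolite")
  stopifnot(n_cohorts >= 1, all(cases_per_cohort >= 1),
            all(controls_per_cohort >= 1),
            n_species >= 1, n_ko >= 1, n_metabolites >= 1,
            zero_inflation_prob >= 0, zero_inflation_prob <= 1,
            gene_content_density >= 0, gene_content_density <= 1,
            prob_enriched >= 0, prob_enriched <= 1)
  if (nd[["species"]] > n_species || nd[["ko"]] > n_ko ||
      nd[["metabolite"]] > n_metabolites) {
    stop("more differential features requested than features available")
  }
  structure(list(n_cohorts = n_cohorts,
                 cases_per_cohort = cases_per_cohort,
                 controls_per_cohort = controls_per_cohort,
                 n_species = n_species, n_ko = n_ko,
                 n_metabolites = n_metabolites,
                 n_differential = nd,
                 effect_size_log10 = effect_size_log10,
                 batch_sd_log10 = batch_sd_log10,
                 zero_inflation_prob = zero_inflation_prob,
                 gene_content_density = gene_content_density,
                 metabolite_coupling_strength = metabolite_coupling_strength,
                 noise_sd = noise_sd,
                 prob_enriched = prob_enriched,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a coupled multi-cohort dataset with planted ground truth
#'
#' @param config a [simulation_config()].
#' @return list with elements `species`, `ko` (both `OmicsMatrix`),
#'   `stratified` (`StratifiedKoMatrix`), `metabolite` (`OmicsMatrix`),
#'   `metadata` (`SampleMetadata` data.frame) and `truth` (list of per-layer
#'   truth tables).
#' @export
simulate_cohort_set <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  seed_state <- .seed_begin(config$seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  cohorts <- sprintf("cohort%02d", seq_len(config$n_cohorts))
  n_per <- config$cases_per_cohort + config$controls_per_cohort
  n_samples <- sum(n_per)

  status <- unlist(lapply(seq_len(config$n_cohorts), function(i) {
    rep(c("case", "control"),
        c(config$cases_per_cohort[i], config$controls_per_cohort[i]))
  }))
  cohort <- rep(cohorts, n_per)
  sample_id <- sprintf("S%04d", seq_len(n_samples))

  sp_ids <- sprintf("sp__Species_%03d", seq_len(config$n_species))
  ko_ids <- sprintf("K%05d", seq_len(config$n_ko))
  mb_ids <- sprintf("HMDB%07d", seq_len(config$n_metabolites))

  ## --- species layer -------------------------------------------------------
  # Planted species are drawn from the upper-middle abundance band (50th-85th
  # percentile of the baseline distribution). Shifting a dominant taxon would
  # redistribute mass across every other feature under compositional closure
  # and turn null features into apparent signals, while rare taxa sit near
  # the detection floor where downstream log pseudo-counts swallow the
  # planted shift; disease marker species in real profiles are typically
  # well-detected mid-abundance commensals.
  n_diff_sp <- config$n_differential[["species"]]
  base_mu <- stats::rnorm(config$n_species, mean = 0, sd = 0.7)
  diff_sp <- integer(0)
  dir_sp <- rep(0, config$n_species)
  if (n_diff_sp > 0) {
    qs <- stats::quantile(base_mu, c(0.5, 0.85))
    pool <- which(base_mu >= qs[1L] & base_mu <= qs[2L])
    if (length(pool) < n_diff_sp) {
      pool <- order(abs(base_mu - stats::median(base_mu)))[seq_len(n_diff_sp)]
    }
    diff_sp <- sort(sample(pool, n_diff_sp))
    dir_sp[diff_sp] <- ifelse(stats::runif(n_diff_sp) < config$prob_enriched, 1, -1)
  }
  batch <- matrix(stats::rnorm(config$n_species * config$n_cohorts,
                               sd = config$batch_sd_log10),
                  nrow = config$n_species)
  is_case <- status == "case"
  loga <- matrix(stats::rnorm(config$n_species * n_samples), config$n_species) +
    base_mu
  loga <- loga + batch[, match(cohort, cohorts), drop = FALSE]
  loga <- loga + outer(dir_sp * config$effect_size_log10, as.numeric(is_case))
  ab <- 10^loga
  if (config$zero_inflation_prob > 0) {
    drop <- matrix(stats::runif(length(ab)) < config$zero_inflation_prob,
                   nrow = nrow(ab))
    ab[drop] <- 0
  }
  # detection-limit guard: keep the largest value of an all-zero sample
  zero_cols <- colSums(ab) == 0
  if (any(zero_cols)) {
    for (j in which(zero_cols)) {
      i <- which.max(loga[, j])
      ab[i, j] <- 10^loga[i, j]
    }
  }
  ab <- sweep(ab, 2, colSums(ab), "/")
  dimnames(ab) <- list(sp_ids, sample_id)

  ## --- KO layer ------------------------------------------------------------
  n_diff_ko <- config$n_differential[["ko"]]
  diff_ko <- seq_len(n_diff_ko)
  dir_ko <- rep(0, config$n_ko)
  # differential KOs draw contributors only from planted species that share a
  # direction, so KO shifts are inherited through the gene-content coupling;
  # null KOs draw from non-differential species.
  G <- matrix(0, config$n_species, config$n_ko,
              dimnames = list(sp_ids, ko_ids))
  null_sp <- setdiff(seq_len(config$n_species), diff_sp)
  pick <- function(pool, density) {
    k <- max(1L, stats::rbinom(1L, length(pool), density))
    sample(pool, min(k, length(pool)))
  }
  if (config$gene_content_density > 0) for (k in seq_len(config$n_ko)) {
    if (k %in% diff_ko && n_diff_sp > 0) {
      d <- ifelse(stats::runif(1) < config$prob_enriched, 1, -1)
      pool <- diff_sp[dir_sp[diff_sp] == d]
      if (!length(pool)) { pool <- diff_sp; d <- dir_sp[pool[1L]] }
      dir_ko[k] <- d
      G[pick(pool, max(config$gene_content_density, 0.5)), k] <- 1
    } else if (length(null_sp)) {
      G[pick(null_sp, config$gene_content_density), k] <- 1
    } else {
      G[pick(seq_len(config$n_species), config$gene_content_density), k] <- 1
    }
  }
  ko_raw <- crossprod(G, ab)                       # n_ko x n_samples
  ko_tot <- colSums(ko_raw)
  ko_tot[ko_tot == 0] <- 1                         # degenerate: all-zero KO layer
  ko <- sweep(ko_raw, 2, ko_tot, "/")
  dimnames(ko) <- list(ko_ids, sample_id)

  # stratified store: per-species terms divided by the same per-sample total
  strat <- NULL
  nz <- which(G != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    contrib <- ab[nz[, 1L], , drop = FALSE] /
      matrix(ko_tot, nrow(nz), n_samples, byrow = TRUE)
    strat <- stratified_ko_matrix(data.frame(
      ko_id = rep(ko_ids[nz[, 2L]], n_samples),
      contributor = rep(sp_ids[nz[, 1L]], n_samples),
      sample_id = rep(sample_id, each = nrow(nz)),
      abundance = as.vector(contrib),
      stringsAsFactors = FALSE))
  }

  ## --- metabolite layer ----------------------------------------------------
  n_diff_mb <- config$n_differential[["metabolite"]]
  diff_mb <- seq_len(n_diff_mb)
  dir_mb <- rep(0, config$n_metabolites)
  log_ko <- log10(ko + 1e-9)
  z_ko <- t(scale(t(log_ko)))
  z_ko[!is.finite(z_ko)] <- 0
  coupled <- vector("list", config$n_metabolites)
  baseline <- stats::rnorm(config$n_metabolites, mean = 3, sd = 1)
  mb <- matrix(0, config$n_metabolites, n_samples,
               dimnames = list(mb_ids, sample_id))
  null_ko <- setdiff(seq_len(config$n_ko), diff_ko)
  for (m in seq_len(config$n_metabolites)) {
    if (m %in% diff_mb && n_diff_ko > 0) {
      d <- ifelse(stats::runif(1) < config$prob_enriched, 1, -1)
      pool <- diff_ko[dir_ko[diff_ko] == d]
      if (!length(pool)) { pool <- diff_ko; d <- dir_ko[pool[1L]] }
      dir_mb[m] <- d
      ks <- sample(pool, min(length(pool), sample(1:3, 1)))
    } else if (length(null_ko)) {
      ks <- sample(null_ko, min(length(null_ko), sample(1:3, 1)))
    } else {
      ks <- sample(seq_len(config$n_ko), 1L)
    }
    coupled[[m]] <- ko_ids[ks]
    signal <- colMeans(z_ko[ks, , drop = FALSE])
    mb[m, ] <- baseline[m] +
      config$metabolite_coupling_strength * signal +
      stats::rnorm(n_samples, sd = config$noise_sd)
  }
  mb_conc <- 2^mb                                  # concentration scale, umol/g

  ## --- metadata (confounder-free by default) -------------------------------
  metadata <- data.frame(
    sample_id = sample_id,
    cohort = cohort,
    status = factor(status, levels = c("control", "case")),
    subtype = ifelse(is_case, sample(c("UC", "CD"), n_samples, replace = TRUE),
                     NA_character_),
    age = round(stats::rnorm(n_samples, 45, 12), 1),
    gender = sample(c("female", "male"), n_samples, replace = TRUE),
    bmi = round(stats::rnorm(n_samples, 23, 3), 1),
    antibiotic_use = FALSE,
    timepoint_index = 1L,
    stringsAsFactors = FALSE)
  class(metadata) <- c("SampleMetadata", "data.frame")

  truth_layer <- function(ids, dirv, shift) {
    data.frame(feature_id = ids,
               is_differential = dirv != 0,
               direction = ifelse(dirv > 0, "case_enriched",
                                  ifelse(dirv < 0, "case_depleted", NA_character_)),
               true_shift = dirv * shift,
               stringsAsFactors = FALSE)
  }
  truth <- list(
    species = truth_layer(sp_ids, dir_sp, config$effect_size_log10),
    ko = truth_layer(ko_ids, dir_ko, config$effect_size_log10),
    metabolite = truth_layer(mb_ids, dir_mb,
                             config$metabolite_coupling_strength),
    ko_contributors = lapply(stats::setNames(seq_len(config$n_ko), ko_ids),
                             function(k) sp_ids[G[, k] != 0]),
    metabolite_coupled_kos = stats::setNames(coupled, mb_ids))

  list(species = omics_matrix(ab, "species"),
       ko = omics_matrix(ko, "ko"),
       stratified = strat,
       metabolite = omics_matrix(mb_conc, "metabolite"),
       metadata = metadata,
       truth = truth)
}

#' Inject a confounding signal into simulated matrices
#'
#' Adds a factor-level-specific offset (log10 scale) of the given magnitude to
#' a feature subset, then renormalizes compositional layers. With two factor
#' levels the offsets are +strength/2 and -strength/2.
#'
#' @param x an `OmicsMatrix` in raw (relative-abundance) state.
#' @param metadata a `SampleMetadata` data.frame.
#' @param factor_name metadata column to confound by.
#' @param strength offset magnitude in log10 units; 0 returns the input
#'   unchanged.
#' @param features feature ids (or indices) to perturb; default: all.
#' @return the modified `OmicsMatrix`.
#' @export
inject_confounding <- function(x, metadata, factor_name, strength,
                               features = NULL) {
  if (!factor_name %in% names(metadata)) {
    stop("unknown metadata factor: ", factor_name)
  }
  if (strength == 0) return(x)
  v <- x$values
  if (is.null(features)) features <- rownames(v)
  lev <- factor(metadata[[factor_name]][match(colnames(v), metadata$sample_id)])
  offs <- (seq_along(levels(lev)) - mean(seq_along(levels(lev)))) * strength
  shift <- offs[as.integer(lev)]
  v[features, ] <- v[features, , drop = FALSE] *
    matrix(10^shift, length(features), ncol(v), byrow = TRUE)
  if (x$namespace %in% c("species", "ko", "eggnog")) {
    v <- sweep(v, 2, colSums(v), "/")
  }
  x$values <- v
  x
}
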