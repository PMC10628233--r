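# Shared fixture builders. Everything is generated in code at test time.

tiny_sim <- function(seed = 1L, ...) {
  simulate_cohort_set(simulation_config(
    n_cohorts = 3, cases_per_cohort = 14, controls_per_cohort = 7,
    n_species = 60, n_ko = 30, n_metabolites = 15,
    n_differential = c(species = 6, ko = 4, metabolite = 3),
    seed = seed, ...))
}

toy_matrix <- function(values, ids = NULL, samples = NULL,
                       namespace = "species", state = "raw") {
  v <- as.matrix(values)
  rownames(v) <- ids %||% paste0("f", seq_len(nrow(v)))
  colnames(v) <- samples %||% paste0("s", seq_len(ncol(v)))
  omics_matrix(v, namespace = namespace, transform_state = state)
}

toy_metadata <- function(n_per_cohort = c(A = 4, B = 4),
                         status = NULL) {
  n <- sum(n_per_cohort)
  md <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    cohort = rep(names(n_per_cohort), n_per_cohort),
    status = status %||% rep_len(c("case", "control"), n),
    timepoint_index = 1L,
    stringsAsFactors = FALSE)
  md$status <- factor(md$status, levels = c("control", "case"))
  class(md) <- c("SampleMetadata", "data.frame")
  md
}

toy_reactions <- function() {
  reaction_table(data.frame(
    ko_id = c("K1", "K1", "K2", "K3", "K4"),
    reaction_id = c("R1", "R2", "R3", "R4", "R5"),
    substrates = c("M1", "M2", "M1;M3", "M4", "M5"),
    products = c("M2", "M6", "M6", "M5", "M7"),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
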