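#' Sample filters: first time point and control:case ratio band
#'
#' Applies the study-design filters: keep only each subject's first sampling
#' (`timepoint_index == 1`) and, within each cohort whose controls exceed the
#' target band, randomly subsample controls so that the cases:controls ratio
#' falls inside the band (default 2 to 3 cases per control, i.e. controls end
#' up between cases/3 and cases/2). Subsampling is uniform without
#' replacement and fully determined by `seed`.
#'
#' @param x an `OmicsMatrix`.
#' @param metadata `SampleMetadata` covering all samples of `x`.
#' @param first_timepoint_only drop repeat samplings.
#' @param ratio_band numeric length-2, cases-per-control band (low, high).
#' @param seed integer seed for the control subsampling.
#' @return list with elements `matrix` and `metadata`, both restricted to the
#'   retained samples. Cohorts left without both statuses are flagged in
#'   attribute `dropped_cohorts` (with a warning) for exclusion from
#'   supervised stages.
#' @export
filter_samples <- function(x, metadata, first_timepoint_only = TRUE,
                           ratio_band = c(2, 3), seed = 1L) {
  md <- metadata[match(sample_ids(x), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  keep <- rep(TRUE, nrow(md))
  if (first_timepoint_only && "timepoint_index" %in% names(md)) {
    keep <- md$timepoint_index == 1L
  }
  md <- md[keep, , drop = FALSE]

  seed_state <- .seed_begin(seed)
  on.exit(.seed_end(seed_state), add = TRUE)
  drop_ids <- character(0)
  for (co in unique(md$cohort)) {
    rows <- md[md$cohort == co, , drop = FALSE]
    n_case <- sum(rows$status == "case")
    n_ctrl <- sum(rows$status == "control")
    if (n_case == 0L || n_ctrl == 0L) next
    # controls above the band (fewer than ratio_band[1] cases per control)
    if (n_ctrl > floor(n_case / ratio_band[1L])) {
      target <- floor(n_case / ratio_band[1L])
      if (target >= 1L) {
        ctrl_ids <- rows$sample_id[rows$status == "control"]
        keep_ctrl <- sample(ctrl_ids, target)
        drop_ids <- c(drop_ids, setdiff(ctrl_ids, keep_ctrl))
      }
    }
  }
  md <- md[!md$sample_id %in% drop_ids, , drop = FALSE]

  dropped_cohorts <- character(0)
  for (co in unique(md$cohort)) {
    st <- md$status[md$cohort == co]
    if (!all(c("control", "case") %in% as.character(st))) {
      dropped_cohorts <- c(dropped_cohorts, co)
    }
  }
  if (length(dropped_cohorts)) {
    warning("cohort(s) without both statuses, excluded from supervised stages: ",
            paste(dropped_cohorts, collapse = ", "))
  }
  out <- subset_omics(x, samples = md$sample_id)
  attr(md, "dropped_cohorts") <- dropped_cohorts
  list(matrix = out, metadata = md)
}

#' Low-abundance and zero-variance feature filter
#'
#' Drops features whose maximum abundance across samples falls below the
#' cutoff, plus features with zero variance (constants carry no signal and
#' break standardization). Dropped ids are recorded in the
#' `dropped_features` attribute for the run manifest.
#'
#' @param x raw/filtered `OmicsMatrix`.
#' @param max_abundance_cutoff drop a feature if `max(abundance) <` cutoff.
#'   Printed defaults: 1e-6 for functional (KO/EggNOG) profiles; species
#'   profiles are typically filtered by prevalence upstream, so the default
#'   here is 0 (variance filter only).
#' @return filtered `OmicsMatrix` (transform state `filtered`).
#' @export
filter_features <- function(x, max_abundance_cutoff = 0) {
  v <- x$values
  mx <- apply(v, 1L, max)
  vr <- apply(v, 1L, stats::var)
  keep <- mx >= max_abundance_cutoff & vr > 0
  if (!any(keep)) stop("all features removed by filtering")
  dropped <- rownames(v)[!keep]
  out <- advance_state(subset_omics(x, features = which(keep)), "filtered")
  attr(out, "dropped_features") <- dropped
  out
}

#' Transform parameters for log + z-score standardization
#'
#' Printed defaults by namespace: species use pseudo-count 1e-5 with log10;
#' functional profiles use pseudo-count 1e-9 with log10; metabolite
#' concentrations use log2 with no pseudo-count (a zero concentration is an
#' error, since targeted panels report positive values).
#'
#' @param namespace feature namespace.
#' @param pseudo_count added before the log; must be > 0 for abundance data.
#' @param log_base 10 or 2.
#' @return list of class `TransformParams`.
#' @export
transform_params <- function(namespace = c("species", "ko", "eggnog", "metabolite"),
                             pseudo_count = NULL, log_base = NULL) {
  namespace <- match.arg(namespace)
  if (is.null(pseudo_count)) {
    pseudo_count <- switch(namespace, species = 1e-5, ko = 1e-9,
                           eggnog = 1e-9, metabolite = 0)
  }
  if (is.null(log_base)) {
    log_base <- switch(namespace, metabolite = 2, 10)
  }
  structure(list(namespace = namespace, pseudo_count = pseudo_count,
                 log_base = log_base),
            class = "TransformParams")
}

#' Log-transform an abundance matrix
#'
#' @param x filtered `OmicsMatrix`.
#' @param params a [transform_params()]; defaults follow the namespace.
#' @return `OmicsMatrix` in `log` state.
#' @export
log_transform <- function(x, params = transform_params(x$namespace)) {
  x <- advance_state(x, "log")          # rejects backward transitions early
  v <- x$values
  if (params$pseudo_count <= 0 && any(v <= 0)) {
    stop("zero or negative values with no pseudo-count; supply pseudo_count > 0")
  }
  x$values <- log(v + params$pseudo_count, base = params$log_base)
  x
}

#' Log + z-score standardization with training-set statistics
#'
#' Values are log-transformed (namespace defaults: log10 with pseudo-count
#' 1e-5 for species, 1e-9 for functional profiles; log2 for metabolites) and
#' standardized per feature using means/SDs estimated on the designated
#' training samples only, so held-out samples never influence the statistics.
#' Features with zero training SD are dropped with a warning.
#'
#' @param x filtered (or log-state) `OmicsMatrix`.
#' @param params a [transform_params()].
#' @param train_sample_ids samples used to estimate the per-feature mean/SD;
#'   default: all samples.
#' @return `OmicsMatrix` in `zscore` state; the frozen statistics are stored
#'   in attribute `zscore_stats` (data.frame feature_id, mean, sd).
#' @export
log_zscore <- function(x, params = transform_params(x$namespace),
                       train_sample_ids = NULL) {
  if (x$transform_state != "log") x <- log_transform(x, params)
  v <- x$values
  if (is.null(train_sample_ids)) train_sample_ids <- colnames(v)
  if (!all(train_sample_ids %in% colnames(v))) {
    stop("train_sample_ids absent from matrix")
  }
  tr <- v[, train_sample_ids, drop = FALSE]
  mu <- rowMeans(tr)
  sd_ <- apply(tr, 1L, stats::sd)
  bad <- !is.finite(sd_) | sd_ <= 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with zero training SD dropped: ",
            paste(utils::head(rownames(v)[bad], 5L), collapse = ", "))
    v <- v[!bad, , drop = FALSE]; mu <- mu[!bad]; sd_ <- sd_[!bad]
  }
  x$values <- (v - mu) / sd_
  x <- advance_state(x, "zscore")
  attr(x, "zscore_stats") <- data.frame(feature_id = rownames(v),
                                        mean = mu, sd = sd_,
                                        row.names = NULL)
  x
}

#' Harmonize metabolite matrices across cohorts to a common HMDB namespace
#'
#' Renames features through a compound-name-to-HMDB map, then restricts every
#' cohort matrix to the intersection of feature sets, emulating the
#' common-metabolite step of multi-cohort metabolomics integration. Unmapped
#' names are excluded (and reported in the `unmapped` attribute). Two input
#' names mapping to one HMDB ID within a cohort is an error unless
#' `aggregate = "mean"`.
#'
#' @param cohort_matrices named list of metabolite `OmicsMatrix` objects.
#' @param name_to_hmdb_map named character vector (input name -> HMDB ID), or
#'   NULL if features are already HMDB IDs.
#' @param aggregate `"error"` (default) or `"mean"` for ambiguous mappings.
#' @return list with `matrices` (aligned list) and `common_feature_ids`.
#' @export
harmonize_metabolites <- function(cohort_matrices, name_to_hmdb_map = NULL,
                                  aggregate = c("error", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(cohort_matrices) < 2L) {
    stop("need at least two cohort matrices to harmonize")
  }
  unmapped <- character(0)
  mapped <- lapply(cohort_matrices, function(m) {
    v <- m$values
    ids <- rownames(v)
    if (!is.null(name_to_hmdb_map)) {
      hm <- unname(name_to_hmdb_map[ids])
      known <- !is.na(hm)
      unmapped <<- union(unmapped, ids[!known])
      v <- v[known, , drop = FALSE]
      hm <- hm[known]
      if (anyDuplicated(hm)) {
        if (aggregate == "error") {
          stop("distinct input names map to one HMDB ID: ",
               paste(unique(hm[duplicated(hm)]), collapse = ", "),
               " (set aggregate = \"mean\" to combine)")
        }
        v <- rowsum(v, group = hm) / as.vector(table(hm)[sort(unique(hm))])
        hm <- rownames(v)
      }
      rownames(v) <- hm
    }
    m$values <- v
    m
  })
  common <- sort(Reduce(intersect, lapply(mapped, feature_ids)))
  if (!length(common)) stop("no common metabolites across cohorts")
  out <- lapply(mapped, function(m) subset_omics(m, features = common))
  res <- list(matrices = out, common_feature_ids = common)
  attr(res, "unmapped") <- unmapped
  res
}
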