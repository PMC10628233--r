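#' Read a feature-by-sample abundance table
#'
#' Understands three dialects: MetaPhlAn-style merged taxonomic tables
#' (clade names with `k__|p__|...` lineages; only rows at the requested rank
#' are kept), HUMAnN-style KO tables (optionally containing species-stratified
#' rows of the form `K00001|g__X.s__Y`), and plain feature x sample TSVs.
#' Percent-scale inputs are detected from the median column sum (within
#' [50, 150]) and rescaled to fractions, because MetaPhlAn emits percentages
#' while renormalized HUMAnN tables emit fractions.
#'
#' @param path TSV file; first column feature id, remaining columns samples.
#' @param namespace feature namespace, see [omics_matrix()].
#' @param dialect one of `"plain_tsv"`, `"metaphlan_merged"`, `"humann_ko"`.
#' @param rank taxonomic rank retained for `metaphlan_merged` (default
#'   `"species"`).
#' @param stratified if TRUE (only for `humann_ko`), also return the
#'   stratified contributor rows.
#' @return an `OmicsMatrix`, or for `stratified = TRUE` a list with elements
#'   `matrix` (unstratified `OmicsMatrix`) and `stratified`
#'   (`StratifiedKoMatrix`).
#' @export
read_abundance_table <- function(path,
                                 namespace = c("species", "ko", "eggnog", "metabolite"),
                                 dialect = c("plain_tsv", "metaphlan_merged", "humann_ko"),
                                 rank = "species",
                                 stratified = FALSE) {
  namespace <- match.arg(namespace)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty abundance table: ", path)
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stop("non-finite values in abundance table")
  if (any(vals < 0)) stop("negative values in abundance table")

  strat_tab <- NULL
  if (dialect == "metaphlan_merged") {
    keep <- .metaphlan_rank_rows(ids, rank)
    if (!any(keep)) stop("no rows at rank '", rank, "' in ", path)
    vals <- vals[keep, , drop = FALSE]
    ids <- .metaphlan_terminal(ids[keep])
  } else if (dialect == "humann_ko") {
    is_strat <- grepl("|", ids, fixed = TRUE)
    if (any(is_strat) && stratified) {
      parts <- strsplit(ids[is_strat], "|", fixed = TRUE)
      strat_long <- data.frame(
        ko_id = vapply(parts, `[[`, "", 1L),
        contributor = vapply(parts, `[[`, "", 2L),
        stringsAsFactors = FALSE)
      sv <- vals[is_strat, , drop = FALSE]
      strat_tab <- stratified_ko_matrix(data.frame(
        ko_id = rep(strat_long$ko_id, ncol(sv)),
        contributor = rep(strat_long$contributor, ncol(sv)),
        sample_id = rep(colnames(sv), each = nrow(sv)),
        abundance = as.vector(sv),
        stringsAsFactors = FALSE))
    }
    vals <- vals[!is_strat, , drop = FALSE]
    ids <- ids[!is_strat]
    if (!length(ids)) stop("no unstratified rows in ", path)
  }

  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(vals) <- ids

  if (namespace %in% c("species", "ko", "eggnog")) {
    vals <- rescale_percent_columns(vals)
  }
  m <- omics_matrix(vals, namespace = namespace)
  if (stratified) return(list(matrix = m, stratified = strat_tab))
  m
}

# Percent vs fraction detection: median column sum in [50, 150] means the
# table is on the 0-100 scale and is divided by 100. Idempotent: fractions
# have median column sum <= 1 and are left alone.
#' Rescale percent-scale columns to fractions
#'
#' @param vals numeric matrix (features x samples).
#' @return matrix on the fraction scale.
#' @export
rescale_percent_columns <- function(vals) {
  med <- stats::median(colSums(vals))
  if (is.finite(med) && med >= 50 && med <= 150) vals <- vals / 100
  vals
}

.metaphlan_rank_rows <- function(ids, rank) {
  prefix <- switch(rank,
    kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
    family = "f__", genus = "g__", species = "s__", strain = "t__",
    stop("unknown taxonomic rank: ", rank))
  last <- vapply(strsplit(ids, "|", fixed = TRUE),
                 function(p) p[[length(p)]], "")
  startsWith(last, prefix)
}

.metaphlan_terminal <- function(ids) {
  vapply(strsplit(ids, "|", fixed = TRUE), function(p) p[[length(p)]], "")
}

#' Write an abundance table to TSV
#'
#' Values are written with full double precision so that a read/write
#' round-trip reproduces the matrix to better than 1e-12 relative error.
#'
#' @param x an `OmicsMatrix`.
#' @param path output TSV path.
#' @param id_column name of the feature-id column (first column).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, id_column = "feature_id") {
  v <- x$values
  df <- data.frame(id = rownames(v), stringsAsFactors = FALSE)
  names(df) <- id_column
  out <- cbind(df, as.data.frame(format(v, digits = 17, trim = TRUE,
                                        scientific = TRUE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `cohort`, `status`; any other columns are
#' preserved as free covariates. Disease-status labels are mapped to
#' `control`/`case` through a configurable label map, so e.g. "IBD", "CD" and
#' "UC" all become `case` while the subtype is retained when a `subtype`
#' column or a mappable label is present.
#'
#' @param path metadata TSV.
#' @param status_map named character vector mapping raw labels to
#'   `"control"`/`"case"`.
#' @return data.frame of class `SampleMetadata`.
#' @export
read_metadata <- function(path, status_map = default_status_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "cohort", "status")
  for (col in required) {
    if (!col %in% names(md)) stop("metadata lacks required column: ", col)
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  raw_status <- as.character(md$status)
  mapped <- unname(status_map[raw_status])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    stop("unmappable status label(s): ",
         paste(unique(raw_status[unknown]), collapse = ", "))
  }
  if (!"subtype" %in% names(md)) {
    md$subtype <- ifelse(raw_status %in% c("UC", "CD"), raw_status, NA_character_)
  }
  md$status <- factor(mapped, levels = c("control", "case"))
  for (col in c("age", "bmi")) {
    if (col %in% names(md) && !is.numeric(md[[col]])) {
      parsed <- suppressWarnings(as.numeric(md[[col]]))
      bad <- !is.na(md[[col]]) & md[[col]] != "" & is.na(parsed)
      if (any(bad)) {
        warning(sum(bad), " unparseable '", col, "' value(s) set to missing")
      }
      md[[col]] <- parsed
    }
  }
  if ("antibiotic_use" %in% names(md)) {
    md$antibiotic_use <- as.logical(md$antibiotic_use)
  }
  if (!"timepoint_index" %in% names(md)) md$timepoint_index <- 1L
  md$timepoint_index <- as.integer(md$timepoint_index)
  class(md) <- c("SampleMetadata", "data.frame")
  md
}

#' Default disease-status label map
#' @return named character vector.
#' @export
default_status_map <- function() {
  c(control = "control", Control = "control", CONTROL = "control",
    healthy = "control", Healthy = "control", HC = "control",
    nonIBD = "control", "non-IBD" = "control",
    case = "case", Case = "case", CASE = "case",
    IBD = "case", CD = "case", UC = "case", disease = "case")
}

#' Read a KO-to-reaction-to-compound linkage table
#'
#' One row per (KO, reaction) with semicolon-separated substrate and product
#' compound ids sharing the metabolite namespace (HMDB accessions or mapped
#' KEGG compounds). The table emulates a pre-extracted KEGG reaction
#' annotation; no live database access is performed.
#'
#' @param path TSV with columns `ko_id`, `reaction_id`, `substrates`,
#'   `products` and optionally `equation_text`.
#' @param compound_dictionary optional character vector of known compound ids;
#'   unknown ids raise a warning.
#' @return data.frame of class `ReactionTable` with list-columns `substrates`
#'   and `products`.
#' @export
read_reaction_table <- function(path, compound_dictionary = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("ko_id", "reaction_id", "substrates", "products")) {
    if (!col %in% names(tab)) stop("reaction table lacks column: ", col)
  }
  if (!"equation_text" %in% names(tab)) tab$equation_text <- NA_character_
  reaction_table(tab, compound_dictionary = compound_dictionary)
}

#' Construct a ReactionTable from a data.frame
#'
#' @param tab data.frame with columns `ko_id`, `reaction_id`, `substrates`,
#'   `products` (semicolon-separated or list-columns), optional
#'   `equation_text`.
#' @inheritParams read_reaction_table
#' @return a `ReactionTable`.
#' @export
reaction_table <- function(tab, compound_dictionary = NULL) {
  if (is.null(tab$equation_text)) tab$equation_text <- NA_character_
  split_ids <- function(x) {
    if (is.list(x)) return(lapply(x, as.character))
    lapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  subs <- split_ids(tab$substrates)
  prods <- split_ids(tab$products)
  n_sub <- lengths(subs); n_prod <- lengths(prods)
  if (any(n_sub == 0L) || any(n_prod == 0L)) {
    bad <- which(n_sub == 0L | n_prod == 0L)[1L]
    stop("reaction row ", bad, " (", tab$ko_id[bad], ", ", tab$reaction_id[bad],
         ") lacks substrates or products")
  }
  if (!is.null(compound_dictionary)) {
    all_ids <- unique(c(unlist(subs), unlist(prods)))
    unknown <- setdiff(all_ids, compound_dictionary)
    if (length(unknown)) {
      warning("compound id(s) absent from dictionary: ",
              paste(unknown, collapse = ", "))
    }
  }
  out <- data.frame(ko_id = as.character(tab$ko_id),
                    reaction_id = as.character(tab$reaction_id),
                    equation_text = as.character(tab$equation_text),
                    stringsAsFactors = FALSE)
  out$substrates <- subs
  out$products <- prods
  class(out) <- c("ReactionTable", "data.frame")
  out
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and package version. Timestamps are
#' deliberately omitted so that reruns with identical inputs are
#' byte-identical.
#'
#' @param path output JSON path.
#' @param inputs named list/character of input files.
#' @param parameters named list of parameters.
#' @param seed integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), parameters = list(),
                               seed = NULL) {
  manifest <- list(
    package = "ccia",
    version = as.character(utils::packageVersion("ccia")),
    seed = seed,
    inputs = inputs,
    parameters = parameters)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
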