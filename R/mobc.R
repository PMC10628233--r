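#' Link candidate metabolites to enzyme-encoding KO genes
#'
#' Returns every KO with at least one reaction whose substrate or product set
#' intersects the candidate metabolites (undirected membership), together
#' with the linking reactions. Metabolites absent from the reaction table
#' contribute nothing and are reported in the `unlinked` attribute.
#'
#' @param candidate_metabolites compound ids in the reaction table's
#'   namespace (e.g. HMDB accessions).
#' @param reactions a `ReactionTable`.
#' @return data.frame with columns `ko_id`, `reaction_id`,
#'   `linking_compounds` (list-column); the linked KO set is
#'   `unique(result$ko_id)`.
#' @export
link_metabolites_to_kos <- function(candidate_metabolites, reactions) {
  if (!length(candidate_metabolites)) {
    out <- data.frame(ko_id = character(0), reaction_id = character(0))
    out$linking_compounds <- list()
    attr(out, "unlinked") <- character(0)
    return(out)
  }
  cand <- unique(candidate_metabolites)
  hits <- lapply(seq_len(nrow(reactions)), function(i) {
    comp <- union(reactions$substrates[[i]], reactions$products[[i]])
    link <- intersect(cand, comp)
    if (!length(link)) return(NULL)
    r <- data.frame(ko_id = reactions$ko_id[i],
                    reaction_id = reactions$reaction_id[i],
                    stringsAsFactors = FALSE)
    r$linking_compounds <- list(link)
    r
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(ko_id = character(0), reaction_id = character(0))
    out$linking_compounds <- list()
  }
  linked_compounds <- unique(unlist(out$linking_compounds))
  attr(out, "unlinked") <- setdiff(cand, linked_compounds)
  out
}

#' Intersect metabolite-linked KOs with differential KOs
#'
#' @param linked_kos character vector of KO ids (or the output of
#'   [link_metabolites_to_kos()]).
#' @param ko_da `DAResult` from [run_ccia()] on the KO namespace.
#' @param fdr_threshold q cutoff; default: the threshold recorded in `ko_da`.
#' @return data.frame with columns `ko_id`, `direction`, `gfc`, `q_fdr`,
#'   restricted to KOs that are both linked and differential.
#' @export
intersect_with_differential <- function(linked_kos, ko_da,
                                        fdr_threshold = NULL) {
  if (is.data.frame(linked_kos)) linked_kos <- unique(linked_kos$ko_id)
  if (is.null(fdr_threshold)) {
    fdr_threshold <- attr(ko_da, "fdr_threshold", exact = TRUE)
    if (is.null(fdr_threshold)) fdr_threshold <- 0.05
  }
  sig <- ko_da[!is.na(ko_da$q_fdr) & ko_da$q_fdr < fdr_threshold, , drop = FALSE]
  hit <- sig[sig$feature_id %in% linked_kos,
             c("feature_id", "direction", "gfc", "q_fdr"), drop = FALSE]
  names(hit)[1L] <- "ko_id"
  rownames(hit) <- NULL
  hit
}

#' Top taxonomic contributors of a KO gene
#'
#' For each contributing species, the mean across samples (restricted to
#' samples where the unstratified KO abundance is positive) of its share of
#' the KO's abundance; the top `k` species by this mean are returned in
#' non-increasing order. The `unclassified` bucket is reported separately and
#' does not count toward `k`.
#'
#' @param ko_id KO identifier.
#' @param stratified a `StratifiedKoMatrix`.
#' @param ko_matrix unstratified KO `OmicsMatrix` (raw relative abundances).
#' @param k number of contributors returned (default 5).
#' @return data.frame with columns `contributor`, `mean_fraction`, ordered
#'   non-increasing; the unclassified share (or NA) in attribute
#'   `unclassified_fraction`.
#' @export
top_contributors <- function(ko_id, stratified, ko_matrix, k = 5) {
  rows <- stratified[stratified$ko_id == ko_id, , drop = FALSE]
  if (!nrow(rows)) stop("no stratified entries for KO: ", ko_id)
  if (!ko_id %in% feature_ids(ko_matrix)) {
    stop("KO absent from unstratified matrix: ", ko_id)
  }
  tot <- stats::setNames(as.vector(ko_matrix$values[ko_id, , drop = FALSE]),
                         colnames(ko_matrix$values))
  detected <- names(tot)[tot > 0]
  rows <- rows[rows$sample_id %in% detected, , drop = FALSE]
  if (!nrow(rows)) stop("KO never detected: ", ko_id)
  frac <- rows$abundance / tot[rows$sample_id]
  by_sp <- tapply(frac, rows$contributor, function(v) {
    # species with no entry for a detected sample contribute zero there
    sum(v) / length(detected)
  })
  uncl <- unname(by_sp["unclassified"])
  by_sp <- by_sp[names(by_sp) != "unclassified"]
  ord <- order(by_sp, decreasing = TRUE)
  top <- utils::head(ord, k)
  out <- data.frame(contributor = names(by_sp)[top],
                    mean_fraction = unname(by_sp[top]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "unclassified_fraction") <- if (is.null(uncl)) NA_real_ else uncl
  out
}

#' Assemble multi-omics biological correlation (MOBC) map entries
#'
#' One entry per KO that is both metabolite-linked and differential, with
#' every linking reaction expanded: substrates and products carry the
#' differential status of the corresponding metabolite (direction, or "none"
#' when measured but not significant, or "not_measured"), the KO carries its
#' own direction, and the top taxonomic contributors are attached from the
#' stratified store. A compound or KO flagged `validated_in_both` is
#' significant in both omics layers.
#'
#' @param intersected_kos output of [intersect_with_differential()].
#' @param links output of [link_metabolites_to_kos()].
#' @param reactions the `ReactionTable`.
#' @param metabolite_da `DAResult` on the metabolite namespace.
#' @param stratified `StratifiedKoMatrix` (NULL allowed: entries then carry
#'   empty contributor lists, with a warning).
#' @param ko_matrix unstratified KO `OmicsMatrix` (required with
#'   `stratified`).
#' @param metabolite_fdr_threshold q cutoff for compound status; default: the
#'   threshold recorded in `metabolite_da`.
#' @param k_contributors top contributors per KO (default 5).
#' @return list of class `MobcMap`; each element is a `MobcEntry` list with
#'   fields `ko_id`, `ko_direction`, `reaction_id`, `equation_text`,
#'   `substrates`, `products` (data.frames compound/status),
#'   `validated_in_both`, `top_contributors`.
#' @export
assemble_mobc_map <- function(intersected_kos, links, reactions,
                              metabolite_da, stratified = NULL,
                              ko_matrix = NULL,
                              metabolite_fdr_threshold = NULL,
                              k_contributors = 5) {
  if (is.null(metabolite_fdr_threshold)) {
    metabolite_fdr_threshold <- attr(metabolite_da, "fdr_threshold", exact = TRUE)
    if (is.null(metabolite_fdr_threshold)) metabolite_fdr_threshold <- 0.05
  }
  mb_sig <- metabolite_da$feature_id[!is.na(metabolite_da$q_fdr) &
                                       metabolite_da$q_fdr < metabolite_fdr_threshold]
  compound_status <- function(ids) {
    status <- vapply(ids, function(cid) {
      row <- match(cid, metabolite_da$feature_id)
      if (is.na(row)) return("not_measured")
      if (cid %in% mb_sig) return(metabolite_da$direction[row])
      "none"
    }, "")
    data.frame(compound = ids, status = unname(status),
               stringsAsFactors = FALSE)
  }
  if (is.null(stratified)) {
    warning("no stratified data: entries carry empty contributor lists")
  }
  entries <- list()
  for (i in seq_len(nrow(intersected_kos))) {
    ko <- intersected_kos$ko_id[i]
    link_rows <- links[links$ko_id == ko, , drop = FALSE]
    contribs <- if (!is.null(stratified) && !is.null(ko_matrix)) {
      top_contributors(ko, stratified, ko_matrix, k = k_contributors)
    } else {
      data.frame(contributor = character(0), mean_fraction = numeric(0))
    }
    for (j in seq_len(nrow(link_rows))) {
      rx <- link_rows$reaction_id[j]
      ridx <- which(reactions$ko_id == ko & reactions$reaction_id == rx)[1L]
      subs <- compound_status(reactions$substrates[[ridx]])
      prods <- compound_status(reactions$products[[ridx]])
      validated <- any(c(subs$status, prods$status) %in%
                         c("case_enriched", "case_depleted"))
      entries[[length(entries) + 1L]] <- structure(list(
        ko_id = ko,
        ko_direction = intersected_kos$direction[i],
        ko_gfc = intersected_kos$gfc[i],
        reaction_id = rx,
        equation_text = reactions$equation_text[ridx],
        substrates = subs,
        products = prods,
        validated_in_both = validated,
        top_contributors = contribs), class = "MobcEntry")
    }
  }
  structure(entries, class = "MobcMap")
}

#' Export a MOBC map to TSV and JSON
#'
#' The TSV holds one row per (entry, compound role); the JSON round-trips the
#' full entry structure. Output is a pure function of the map: identical
#' inputs produce byte-identical files.
#'
#' @param map a `MobcMap`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @return the flattened data.frame, invisibly.
#' @export
export_mobc_map <- function(map, tsv_path = NULL, json_path = NULL) {
  rows <- lapply(map, function(e) {
    comp <- rbind(cbind(role = "substrate", e$substrates),
                  cbind(role = "product", e$products))
    data.frame(ko_id = e$ko_id, ko_direction = e$ko_direction,
               reaction_id = e$reaction_id, role = comp$role,
               compound = comp$compound, compound_status = comp$status,
               validated_in_both = e$validated_in_both,
               top_contributors = paste(e$top_contributors$contributor,
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, rows)
  if (is.null(flat)) {
    flat <- data.frame(ko_id = character(0), ko_direction = character(0),
                       reaction_id = character(0), role = character(0),
                       compound = character(0), compound_status = character(0),
                       validated_in_both = logical(0),
                       top_contributors = character(0))
  }
  if (!is.null(tsv_path)) {
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(map, unclass), json_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(flat)
}
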