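#' Feature-by-sample omics matrix
#'
#' The central container of the package: a numeric feature x sample matrix
#' carrying a feature namespace (species-level taxa, KO gene families, EggNOG
#' groups, or metabolites) and a transform state that records how far along
#' the preprocessing chain the values are. Taxonomic and functional values are
#' relative abundances (columns sum to at most 1; an unmapped fraction may be
#' absent); metabolite values are concentrations (micromol per gram).
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param namespace one of `"species"`, `"ko"`, `"eggnog"`, `"metabolite"`.
#' @param transform_state one of `"raw"`, `"filtered"`, `"log"`, `"zscore"`.
#'   States only ever advance in that order.
#' @return an object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values,
                         namespace = c("species", "ko", "eggnog", "metabolite"),
                         transform_state = "raw") {
  namespace <- match.arg(namespace)
  transform_state <- match.arg(transform_state, .transform_states)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (length(values) == 0L) stop("empty abundance table")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (transform_state %in% c("raw", "filtered")) {
    if (any(values < 0)) stop("negative values in a raw abundance matrix")
    if (namespace %in% c("species", "ko", "eggnog")) {
      cs <- colSums(values)
      if (any(cs > 1 + 1e-6)) {
        stop("relative-abundance columns must sum to <= 1 (max column sum: ",
             format(max(cs)), ")")
      }
    }
  }
  structure(list(values = values, namespace = namespace,
                 transform_state = transform_state),
            class = "OmicsMatrix")
}

.transform_states <- c("raw", "filtered", "log", "zscore")

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' @export
as.matrix.OmicsMatrix <- function(x, ...) x$values

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("<OmicsMatrix> %s | %d features x %d samples | state: %s\n",
              x$namespace, nrow(x$values), ncol(x$values), x$transform_state))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `OmicsMatrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

# Advance the transform state; transitions only move forward along
# raw -> filtered -> log -> zscore.
advance_state <- function(x, to) {
  from_i <- match(x$transform_state, .transform_states)
  to_i <- match(to, .transform_states)
  if (is.na(to_i)) stop("unknown transform state: ", to)
  if (to_i < from_i) {
    stop("transform state may only advance forward (",
         x$transform_state, " -> ", to, " requested)")
  }
  x$transform_state <- to
  x
}

# Subset an OmicsMatrix, preserving metadata fields.
subset_omics <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  x$values <- v
  x
}

#' Stratified KO contribution table
#'
#' Long-format store of species-stratified functional profiles: one row per
#' (KO, contributing species, sample) with a non-negative abundance. The
#' contributor `"unclassified"` holds the unattributed remainder. Contributor
#' sums are expected to match the unstratified KO value for each
#' (KO, sample) cell.
#'
#' @param entries data.frame with columns `ko_id`, `contributor`, `sample_id`,
#'   `abundance`.
#' @return an object of class `StratifiedKoMatrix` (a data.frame).
#' @export
stratified_ko_matrix <- function(entries) {
  req <- c("ko_id", "contributor", "sample_id", "abundance")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop("stratified table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(entries$abundance < 0)) stop("negative stratified abundances")
  entries <- as.data.frame(entries)[req]
  class(entries) <- c("StratifiedKoMatrix", "data.frame")
  entries
}

#' Check stratified/unstratified consistency
#'
#' Verifies that per-(KO, sample) contributor sums match the unstratified KO
#' matrix within a relative tolerance.
#'
#' @param strat a `StratifiedKoMatrix`.
#' @param ko_matrix the unstratified KO `OmicsMatrix`.
#' @param tol relative tolerance.
#' @return TRUE invisibly, or an error describing the first mismatch.
#' @export
check_stratified_consistency <- function(strat, ko_matrix, tol = 1e-6) {
  sums <- stats::aggregate(abundance ~ ko_id + sample_id, data = strat, FUN = sum)
  v <- ko_matrix$values
  for (i in seq_len(nrow(sums))) {
    ko <- sums$ko_id[i]; s <- sums$sample_id[i]
    if (!ko %in% rownames(v)) next
    ref <- v[ko, s]
    if (abs(sums$abundance[i] - ref) > tol * max(ref, 1e-12)) {
      stop(sprintf("stratified sum for (%s, %s) is %g but unstratified value is %g",
                   ko, s, sums$abundance[i], ref))
    }
  }
  invisible(TRUE)
}
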