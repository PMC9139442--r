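#' Filter genes by counts-per-million expression level
#'
#' Retains genes whose CPM strictly exceeds `cpm_threshold` in at least
#' `ceil(min_fraction * n_samples)` samples (the "at least" fraction is
#' inclusive). CPM is computed against the library sizes of the full,
#' pre-filter matrix, so filtering is idempotent and never reorders the
#' surviving genes.
#'
#' @param counts A [count_matrix].
#' @param cpm_threshold CPM cutoff; the comparison is strict (`>`).
#' @param min_fraction Required fraction of samples in (0, 1].
#' @return A [count_matrix] restricted to the retained genes; the sample set
#'   is unchanged. An empty result is permitted (with a warning).
#' @export
filter_genes_by_cpm <- function(counts, cpm_threshold = 2,
                                min_fraction = 0.10) {
  stopifnot(inherits(counts, "count_matrix"))
  if (cpm_threshold <= 0) stop("`cpm_threshold` must be positive")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]")
  lib <- library_sizes(counts)
  if (any(lib == 0)) stop("zero library size: sample(s) with no reads")
  cpm <- sweep(counts$counts, 2, lib, "/") * 1e6
  need <- ceiling(min_fraction * ncol(counts$counts))
  keep <- rowSums(cpm > cpm_threshold) >= need
  if (!any(keep)) warning("no genes pass the CPM filter")
  count_matrix(counts$counts[keep, , drop = FALSE],
               counts$gene_lengths[keep])
}

#' Convert counts to log2 RPKM
#'
#' RPKM is `count * 1e9 / (library_size * gene_length)`; the returned value
#' is `log2(RPKM + offset)`. Library sizes are the column sums of the
#' supplied matrix. With the default `offset = 1`, zero counts map to 0.
#'
#' @param counts A [count_matrix].
#' @param offset Additive offset inside the log (default 1).
#' @return Log-expression matrix (genes x samples).
#' @export
counts_to_log_rpkm <- function(counts, offset = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- library_sizes(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  rpkm <- counts$counts * 1e9 /
    (rep(lib, each = nrow(counts$counts)) * counts$gene_lengths)
  log2(rpkm + offset)
}

# internal: normalize a replicate map (named vector or two-column
# data.frame sample_id -> group_id) against a set of sample ids
resolve_replicate_map <- function(replicate_map, sample_ids) {
  if (is.data.frame(replicate_map)) {
    if (ncol(replicate_map) < 2)
      stop("replicate map data.frame needs columns sample_id, group_id")
    map <- stats::setNames(as.character(replicate_map[[2]]),
                           as.character(replicate_map[[1]]))
  } else {
    map <- stats::setNames(as.character(replicate_map), names(replicate_map))
  }
  missing <- setdiff(sample_ids, names(map))
  if (length(missing))
    stop("samples without a replicate group: ", paste(missing, collapse = ", "))
  map[sample_ids]
}

#' Merge technical replicates of a log-expression matrix
#'
#' Collapses replicate columns to one column per group by the per-gene
#' median of the replicates' log-expression values.
#'
#' @param expr Log-expression matrix (genes x samples).
#' @param replicate_map Named character vector (`sample_id -> group_id`) or
#'   a two-column data.frame (`sample_id`, `group_id`) covering every
#'   sample.
#' @return Log-expression matrix with one column per replicate group, in
#'   order of first appearance.
#' @export
merge_technical_replicates_expression <- function(expr, replicate_map) {
  check_expression(expr)
  map <- resolve_replicate_map(replicate_map, colnames(expr))
  groups <- unique(unname(map))
  merged <- matrix(unlist(lapply(groups, function(g) {
    cols <- which(map == g)
    if (!length(cols)) stop("empty replicate group: ", g)
    apply(expr[, cols, drop = FALSE], 1, stats::median)
  })), nrow = nrow(expr))
  dimnames(merged) <- list(rownames(expr), groups)
  merged
}

#' Merge technical replicates of a count matrix
#'
#' Collapses replicate columns to one column per group by the per-gene sum
#' of counts, conserving total reads.
#'
#' @inheritParams merge_technical_replicates_expression
#' @param counts A [count_matrix].
#' @return A [count_matrix] with one column per replicate group.
#' @export
merge_technical_replicates_counts <- function(counts, replicate_map) {
  stopifnot(inherits(counts, "count_matrix"))
  map <- resolve_replicate_map(replicate_map, colnames(counts$counts))
  groups <- unique(unname(map))
  merged <- matrix(unlist(lapply(groups, function(g) {
    cols <- which(map == g)
    if (!length(cols)) stop("empty replicate group: ", g)
    rowSums(counts$counts[, cols, drop = FALSE])
  })), nrow = nrow(counts$counts))
  dimnames(merged) <- list(rownames(counts$counts), groups)
  count_matrix(merged, counts$gene_lengths)
}
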