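#' Gene-level count matrix with gene lengths
#'
#' Lightweight container pairing an integer count matrix (genes in rows,
#' samples in columns, both with unique dimnames) with per-gene lengths in
#' base pairs. Gene lengths are required to convert counts to RPKM.
#'
#' @param counts Integer matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids). Values must be non-negative
#'   and integral.
#' @param gene_lengths Positive numeric vector of gene lengths in bp, either
#'   named by gene id or in row order of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `gene_lengths` (named, aligned to rows).
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' cm <- count_matrix(m, c(g1 = 500, g2 = 1000, g3 = 1500))
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  # an empty (fully filtered) gene set is legal; R drops its dimnames to NULL
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("`counts` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in `counts`")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(gene_lengths) != nrow(counts))
    stop("`gene_lengths` must have one entry per gene")
  if (is.null(names(gene_lengths))) {
    names(gene_lengths) <- rownames(counts)
  } else {
    if (!setequal(names(gene_lengths), rownames(counts)))
      stop("`gene_lengths` names do not match gene ids")
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be strictly positive")
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  gene lengths: %d-%d bp\n",
              min(x$gene_lengths), max(x$gene_lengths)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Library sizes of a count matrix
#'
#' Per-sample library size, defined as the column sum of the full count
#' matrix. CPM filtering always uses the pre-filter library sizes.
#'
#' @param counts A [count_matrix].
#' @return Named numeric vector of per-sample totals.
#' @export
library_sizes <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  colSums(counts$counts)
}

# internal: validate a log-expression matrix (plain numeric matrix with
# gene/sample dimnames, finite values)
check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    stop("duplicate gene or sample ids in expression matrix")
  if (!all(is.finite(expr)))
    stop("expression values must be finite")
  invisible(expr)
}
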