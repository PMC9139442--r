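#' Parameters for resampling-based signature derivation
#'
#' The derivation draws `resample_fraction` of the samples (without
#' replacement) `n_resamples` times, ranks genes by their Spearman
#' correlation with the drug-response AUC within each draw, and records how
#' often each gene lands in the extreme `tail_fraction` of the correlation
#' ranking. Genes in a tail in at least `min_frequency` of the draws enter
#' the signature. The defaults (80% draws, 1000 resamples, 3% tails, 90%
#' frequency) are the derivation settings used throughout the package.
#'
#' @param resample_fraction Fraction of samples per draw, in (0, 1].
#' @param n_resamples Number of resampling runs.
#' @param tail_fraction Fraction of genes in each correlation tail, in
#'   (0, 0.5).
#' @param min_frequency Minimum tail-membership frequency (inclusive) for a
#'   gene to enter the signature.
#' @param seed Integer seed controlling the resample draws.
#' @return An object of class `signature_params`.
#' @export
signature_params <- function(resample_fraction = 0.8, n_resamples = 1000,
                             tail_fraction = 0.03, min_frequency = 0.90,
                             seed = 1L) {
  if (resample_fraction <= 0 || resample_fraction > 1)
    stop("`resample_fraction` must be in (0, 1]")
  if (n_resamples < 1) stop("`n_resamples` must be positive")
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("`tail_fraction` must be in (0, 0.5)")
  if (min_frequency < 0 || min_frequency > 1)
    stop("`min_frequency` must be in [0, 1]")
  structure(list(resample_fraction = resample_fraction,
                 n_resamples = as.integer(n_resamples),
                 tail_fraction = tail_fraction,
                 min_frequency = min_frequency,
                 seed = as.integer(seed)),
            class = "signature_params")
}

#' Tail-membership frequencies from resampled Spearman correlations
#'
#' For each resampling run, `floor(resample_fraction * n)` samples are drawn
#' without replacement and each gene's Spearman correlation with the AUC is
#' computed over the draw (average ranks for ties). The `k = max(1,
#' round(tail_fraction * n_genes))` genes with the largest correlations form
#' the top tail, the `k` smallest the bottom tail; ties at a tail boundary
#' are broken by the (stable) gene order of `expr`. A gene whose expression
#' is constant within a draw has no defined correlation there and is absent
#' from both tails of that run.
#'
#' @param expr Log-expression matrix (genes x samples).
#' @param auc Numeric AUC vector; either named by sample id or aligned to
#'   the columns of `expr`.
#' @param params A [signature_params()].
#' @return data.frame with one row per gene: `gene_id`, `freq_top`,
#'   `freq_bottom` (tail-membership counts / `n_resamples`), `median_rho`
#'   (per-gene median correlation across runs where it was defined) and
#'   `n_defined` (runs with a defined correlation).
#' @export
resample_correlations <- function(expr, auc, params = signature_params()) {
  check_expression(expr)
  stopifnot(inherits(params, "signature_params"))
  if (!is.null(names(auc))) {
    if (!setequal(names(auc), colnames(expr)))
      stop("sample ids of `auc` do not match `expr`")
    auc <- auc[colnames(expr)]
  }
  if (length(auc) != ncol(expr))
    stop("`auc` must have one value per sample")
  n <- ncol(expr)
  m <- floor(params$resample_fraction * n)
  if (m < 5) stop("resamples would contain fewer than 5 samples")
  n_genes <- nrow(expr)
  k <- max(1L, round(params$tail_fraction * n_genes))

  texpr <- t(expr)
  top_n <- bottom_n <- defined_n <- numeric(n_genes)
  rho_runs <- matrix(NA_real_, n_genes, params$n_resamples)
  withr::with_seed(params$seed, {
    for (b in seq_len(params$n_resamples)) {
      idx <- sample.int(n, m)
      rho <- suppressWarnings(
        stats::cor(texpr[idx, , drop = FALSE], auc[idx],
                   method = "spearman"))[, 1]
      rho_runs[, b] <- rho
      valid <- which(!is.na(rho))
      defined_n[valid] <- defined_n[valid] + 1
      kk <- min(k, length(valid))
      if (kk > 0) {
        top <- valid[order(rho[valid], decreasing = TRUE)][seq_len(kk)]
        bottom <- valid[order(rho[valid])][seq_len(kk)]
        top_n[top] <- top_n[top] + 1
        bottom_n[bottom] <- bottom_n[bottom] + 1
      }
    }
  })
  data.frame(gene_id = rownames(expr),
             freq_top = top_n / params$n_resamples,
             freq_bottom = bottom_n / params$n_resamples,
             median_rho = apply(rho_runs, 1, stats::median, na.rm = TRUE),
             n_defined = defined_n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive a drug efficacy signature from tail frequencies
#'
#' Genes whose top-tail frequency reaches `min_frequency` form the
#' up-regulated set (expression positively correlated with sensitivity);
#' genes whose bottom-tail frequency reaches it form the down-regulated
#' set. With `tail_fraction < 0.5` and `min_frequency > 0.5` the sets are
#' disjoint by construction; in degenerate settings a gene qualifying for
#' both is assigned to the tail with the higher frequency (ties resolved by
#' the sign of its median correlation).
#'
#' @param freq data.frame from [resample_correlations()].
#' @param params The [signature_params()] used to produce `freq`.
#' @param drug_id Drug identifier stored in the signature.
#' @return An object of class `drug_signature`: list with `drug_id`,
#'   `up_genes`, `down_genes`, and per-gene `frequencies` (the rows of
#'   `freq` for signature members).
#' @export
derive_signature <- function(freq, params = signature_params(),
                             drug_id = "drug") {
  stopifnot(is.data.frame(freq),
            all(c("gene_id", "freq_top", "freq_bottom", "median_rho") %in%
                  names(freq)))
  up <- freq$freq_top >= params$min_frequency & freq$freq_top > 0
  down <- freq$freq_bottom >= params$min_frequency & freq$freq_bottom > 0
  both <- up & down
  if (any(both)) {
    to_up <- freq$freq_top[both] > freq$freq_bottom[both] |
      (freq$freq_top[both] == freq$freq_bottom[both] &
         freq$median_rho[both] >= 0)
    down[both][to_up] <- FALSE
    up[both][!to_up] <- FALSE
  }
  if (!any(up) && !any(down))
    warning(sprintf("empty signature for %s", drug_id))
  sig <- structure(list(drug_id = drug_id,
                        up_genes = freq$gene_id[up],
                        down_genes = freq$gene_id[down],
                        frequencies = freq[up | down, , drop = FALSE]),
                   class = "drug_signature")
  sig
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("drug_signature for %s: %d up, %d down genes\n",
              x$drug_id, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Construct a drug efficacy signature from explicit gene sets
#'
#' Convenience constructor for scoring with externally defined (or
#' ground-truth) up/down sets, bypassing derivation.
#'
#' @param drug_id Drug identifier.
#' @param up_genes,down_genes Disjoint character vectors of gene ids.
#' @return A `drug_signature`.
#' @export
drug_signature <- function(drug_id, up_genes = character(),
                           down_genes = character()) {
  if (length(intersect(up_genes, down_genes)))
    stop("up and down gene sets must be disjoint")
  structure(list(drug_id = drug_id,
                 up_genes = as.character(up_genes),
                 down_genes = as.character(down_genes),
                 frequencies = NULL),
            class = "drug_signature")
}
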