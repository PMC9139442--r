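#' Rank-based single-sample signature score (singscore)
#'
#' Scores one expression profile against a bidirectional signature using
#' only the within-sample ranks of its genes, so the score is invariant to
#' any strictly increasing transform of the profile.
#'
#' All `n` profile genes are ranked ascending with average ranks for ties.
#' For a gene set of size `m`, the mean rank of its members is normalized by
#' the theoretical extremes `r_min = (m + 1) / 2` and
#' `r_max = (2n - m + 1) / 2` and centered: the component is
#' `(rbar - r_min) / (r_max - r_min) - 0.5`, lying in `[-0.5, 0.5]`. The up
#' component uses the ranks directly; the down component uses reversed
#' ranks (`n - rank + 1`), so concerted down-regulation of the down set also
#' scores positively. The total score is the sum of the components present
#' (range `[-1, 1]` for a bidirectional signature).
#'
#' @param profile Named numeric vector of (log) expression values for one
#'   sample; at least 2 genes.
#' @param signature A [drug_signature].
#' @return List of class `score_result`: `total_score`, `up_score`,
#'   `down_score` (`NA` for an absent direction), `n_up_used`,
#'   `n_down_used` (signature genes found in the profile).
#' @examples
#' sig <- drug_signature("d", up_genes = c("g3", "g4"))
#' singscore(c(g1 = 5, g2 = 6, g3 = 7, g4 = 8), sig)$up_score  # 0.5
#' @export
singscore <- function(profile, signature) {
  stopifnot(inherits(signature, "drug_signature"))
  if (is.null(names(profile)) || length(profile) < 2)
    stop("`profile` must be a named vector of at least 2 genes")
  n <- length(profile)
  up <- intersect(signature$up_genes, names(profile))
  down <- intersect(signature$down_genes, names(profile))
  if (!length(up) && !length(down))
    stop("no signature genes present in the profile")
  r <- rank(profile)  # average ranks for ties
  component <- function(ranks, set) {
    m <- length(set)
    if (m == 0) return(NA_real_)
    if (m >= n) {
      warning("gene set covers the whole profile; component undefined, 0 used")
      return(0)
    }
    rbar <- mean(ranks[set])
    r_min <- (m + 1) / 2
    r_max <- (2 * n - m + 1) / 2
    (rbar - r_min) / (r_max - r_min) - 0.5
  }
  up_score <- component(r, up)
  down_score <- component(n - r + 1, down)
  total <- sum(c(up_score, down_score), na.rm = TRUE)
  structure(list(total_score = total, up_score = up_score,
                 down_score = down_score,
                 n_up_used = length(up), n_down_used = length(down)),
            class = "score_result")
}

#' Stable-gene-anchored signature score (stingscore)
#'
#' Variant of [singscore()] that ranks each signature gene against a small
#' panel of stably expressed anchor genes instead of the whole profile,
#' making scores comparable across datasets with different gene coverage or
#' background distributions. For each signature gene `g`, the anchor
#' percentile is `p(g) = (#anchors below g + 0.5 * #anchors tied with g) /
#' panel size`. The up component is `mean(p(up)) - 0.5`, the down component
#' `0.5 - mean(p(down))`, and the total their sum.
#'
#' @inheritParams singscore
#' @param panel Character vector of anchor gene ids (all must be present in
#'   the profile; anchors are mandatory).
#' @return A `score_result` as in [singscore()].
#' @export
stingscore <- function(profile, signature, panel) {
  stopifnot(inherits(signature, "drug_signature"))
  if (is.null(names(profile))) stop("`profile` must be a named vector")
  if (!length(panel)) stop("`panel` must contain at least one anchor gene")
  missing_panel <- setdiff(panel, names(profile))
  if (length(missing_panel))
    stop("anchor gene(s) missing from profile: ",
         paste(missing_panel, collapse = ", "))
  overlap <- intersect(panel, c(signature$up_genes, signature$down_genes))
  if (length(overlap))
    stop("anchor panel overlaps signature genes: ",
         paste(overlap, collapse = ", "))
  up <- intersect(signature$up_genes, names(profile))
  down <- intersect(signature$down_genes, names(profile))
  if (!length(up) && !length(down))
    stop("no signature genes present in the profile")
  anchors <- profile[panel]
  pctl <- function(v) {
    (sum(anchors < v) + 0.5 * sum(anchors == v)) / length(anchors)
  }
  up_score <- if (length(up)) mean(vapply(profile[up], pctl, 0)) - 0.5
    else NA_real_
  down_score <- if (length(down)) 0.5 - mean(vapply(profile[down], pctl, 0))
    else NA_real_
  total <- sum(c(up_score, down_score), na.rm = TRUE)
  structure(list(total_score = total, up_score = up_score,
                 down_score = down_score,
                 n_up_used = length(up), n_down_used = length(down)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result: total %.4f (up %.4f, down %.4f; %d/%d genes)\n",
              x$total_score, x$up_score, x$down_score,
              x$n_up_used, x$n_down_used))
  invisible(x)
}

#' Score every sample of an expression matrix against a signature
#'
#' @param expr Log-expression matrix (genes x samples).
#' @param signature A [drug_signature].
#' @param method `"singscore"` (default) or `"stingscore"`.
#' @param panel Anchor gene ids, required for `"stingscore"`.
#' @return data.frame with one row per sample (column order preserved):
#'   `sample_id`, `total_score`, `up_score`, `down_score`, `n_up_used`,
#'   `n_down_used`. A per-sample scoring failure is rethrown with the
#'   sample id.
#' @export
score_matrix <- function(expr, signature,
                         method = c("singscore", "stingscore"),
                         panel = NULL) {
  check_expression(expr)
  method <- match.arg(method)
  if (method == "stingscore" && is.null(panel))
    stop("`panel` is required for stingscore")
  rows <- lapply(colnames(expr), function(s) {
    res <- tryCatch(
      switch(method,
             singscore = singscore(expr[, s], signature),
             stingscore = stingscore(expr[, s], signature, panel)),
      error = function(e) stop("sample ", s, ": ", conditionMessage(e),
                               call. = FALSE))
    data.frame(sample_id = s, total_score = res$total_score,
               up_score = res$up_score, down_score = res$down_score,
               n_up_used = res$n_up_used, n_down_used = res$n_down_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
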