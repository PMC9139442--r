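#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via [stats::cor()].
#' Returns `NA` (with a warning) when either vector is constant, where the
#' correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Concordance index between predicted and observed values
#'
#' Over all unordered sample pairs whose observed values differ, a pair is
#' concordant (scores 1) when the predictions order the samples the same
#' way as the observations, discordant (0) when reversed, and tied
#' predictions score 0.5. Pairs with tied observed values are excluded. The
#' CI is the mean pair score: 1 for identical orderings, 0 for fully
#' reversed, 0.5 for unrelated orderings.
#'
#' @param predicted,observed Numeric vectors of equal length >= 2.
#' @return CI in `[0, 1]`, or `NA_real_` (with a warning) when all observed
#'   values are tied.
#' @export
concordance_index <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  n <- length(predicted)
  if (n < 2) stop("need at least 2 observations")
  d_obs <- sign(outer(observed, observed, "-"))
  d_pred <- sign(outer(predicted, predicted, "-"))
  use <- upper.tri(d_obs) & d_obs != 0
  if (!any(use)) {
    warning("all observed values tied: concordance index undefined")
    return(NA_real_)
  }
  agree <- d_obs[use] * d_pred[use]
  mean(ifelse(agree > 0, 1, ifelse(agree < 0, 0, 0.5)))
}

#' Evaluate predictions against observed response in one dataset
#'
#' @param predicted,observed Aligned numeric vectors.
#' @param drug_id,dataset_id Identifiers stamped on the row.
#' @return One-row data.frame: `drug_id`, `dataset_id`, `rho`
#'   (Spearman), `ci` (concordance index), `rmse`, `mae`, `n_samples`.
#' @export
evaluate_predictions <- function(predicted, observed, drug_id = "drug",
                                 dataset_id = "dataset") {
  m <- regression_metrics(predicted, observed)
  data.frame(drug_id = drug_id, dataset_id = dataset_id,
             rho = suppressWarnings(spearman_rho(predicted, observed)),
             ci = suppressWarnings(concordance_index(predicted, observed)),
             rmse = m$rmse, mae = m$mae, n_samples = length(observed),
             stringsAsFactors = FALSE)
}

#' Classify a drug's prediction confidence from per-dataset evaluations
#'
#' A drug is `high` confidence when any test dataset reaches
#' `rho >= rho_high` or `ci >= ci_high`; `low` when every dataset fails
#' both lower thresholds (`rho < rho_low` or absent, and `ci < ci_low` or
#' absent); otherwise `medium`. The tier is monotone: raising any
#' correlation never lowers it.
#'
#' @param evaluations data.frame with columns `rho` and optionally `ci`
#'   (NA = absent), one row per test dataset.
#' @param rho_high,ci_high Thresholds for high confidence (defaults 0.4 and
#'   0.65).
#' @param rho_low,ci_low Thresholds below which a dataset counts toward low
#'   confidence (defaults 0.3 and 0.6).
#' @return One of `"high"`, `"medium"`, `"low"`.
#' @export
classify_confidence <- function(evaluations, rho_high = 0.4, ci_high = 0.65,
                                rho_low = 0.3, ci_low = 0.6) {
  if (!is.data.frame(evaluations) || nrow(evaluations) == 0)
    stop("need at least one dataset evaluation")
  rho <- evaluations$rho
  ci <- if ("ci" %in% names(evaluations)) evaluations$ci
    else rep(NA_real_, nrow(evaluations))
  high <- (!is.na(rho) & rho >= rho_high) | (!is.na(ci) & ci >= ci_high)
  low <- (is.na(rho) | rho < rho_low) & (is.na(ci) | ci < ci_low)
  if (any(high)) "high" else if (all(low)) "low" else "medium"
}

#' Drug-similarity matrices from observed response and from signatures
#'
#' Response similarity between two drugs is the Spearman correlation of
#' their AUC profiles over the samples screened for both (requiring at
#' least `min_shared` shared samples); each off-diagonal entry carries a
#' two-sided significance flag at `alpha` from [stats::cor.test()].
#' Signature similarity is the Jaccard index `|A n B| / |A u B|` of the two
#' drugs' gene sets (the union of up and down genes per drug by default, or
#' each tail separately).
#'
#' @param auc_table data.frame or matrix, samples x drugs, `NA` where a
#'   sample was not screened for a drug. Row names (or a `sample_id`
#'   column) identify samples.
#' @param signatures List of [drug_signature] objects (names or `drug_id`s
#'   must match `auc_table` columns for drugs present in both).
#' @param alpha Significance level for the response-correlation flags.
#' @param separate_tails If `TRUE`, Jaccard is returned separately for up
#'   and down sets.
#' @param min_shared Minimum pairwise-complete samples for a correlation.
#' @return List: `response_rho`, `response_p`, `response_significant`
#'   (symmetric drug x drug matrices, unit/zero diagonal, `NA` where
#'   coverage is insufficient) and `signature_jaccard` (matrix, or a list
#'   of `up`/`down` matrices when `separate_tails`).
#' @export
drug_similarity <- function(auc_table, signatures = NULL, alpha = 0.05,
                            separate_tails = FALSE, min_shared = 3) {
  if (is.data.frame(auc_table) && "sample_id" %in% names(auc_table)) {
    rownames(auc_table) <- auc_table$sample_id
    auc_table$sample_id <- NULL
  }
  auc <- as.matrix(auc_table)
  drugs <- colnames(auc)
  if (length(drugs) < 2) stop("need at least 2 drugs")
  nd <- length(drugs)
  rho <- p <- matrix(NA_real_, nd, nd, dimnames = list(drugs, drugs))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(nd - 1)) {
    for (j in seq(i + 1, nd)) {
      ok <- stats::complete.cases(auc[, i], auc[, j])
      if (sum(ok) < min_shared) next
      ct <- suppressWarnings(
        stats::cor.test(auc[ok, i], auc[ok, j], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  out <- list(response_rho = rho, response_p = p,
              response_significant = p <= alpha)
  if (!is.null(signatures)) {
    ids <- vapply(signatures, `[[`, "", "drug_id")
    names(signatures) <- ids
    jacc <- function(a, b) {
      u <- length(union(a, b))
      if (u == 0) return(NA_real_)
      length(intersect(a, b)) / u
    }
    jmat <- function(getter) {
      m <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
      for (a in ids) for (b in ids)
        m[a, b] <- jacc(getter(signatures[[a]]), getter(signatures[[b]]))
      m
    }
    out$signature_jaccard <- if (separate_tails) {
      list(up = jmat(function(s) s$up_genes),
           down = jmat(function(s) s$down_genes))
    } else {
      jmat(function(s) c(s$up_genes, s$down_genes))
    }
  }
  out
}

#' Stratify samples by extreme signature scores
#'
#' Assigns each sample to `bottom` (score at or below the `lower_q`
#' quantile), `top` (at or above the `upper_q` quantile) or `middle`.
#' Quantiles use linear interpolation ([stats::quantile()] type 7). With
#' degenerate (constant) scores all samples land in a single tier, with a
#' warning.
#'
#' @param scores Numeric vector (optionally named by sample).
#' @param lower_q,upper_q Quantile cutoffs (defaults 0.10 and 0.90).
#' @return Factor of tiers (`bottom`, `middle`, `top`) aligned with
#'   `scores`.
#' @export
stratify_by_score <- function(scores, lower_q = 0.10, upper_q = 0.90) {
  if (lower_q >= upper_q) stop("lower_q must be below upper_q")
  q <- stats::quantile(scores, c(lower_q, upper_q), names = FALSE, type = 7)
  tier <- rep("middle", length(scores))
  tier[scores <= q[1]] <- "bottom"
  tier[scores >= q[2]] <- "top"
  if (q[1] == q[2])
    warning("degenerate score distribution: tiers collapse")
  factor(stats::setNames(tier, names(scores)),
         levels = c("bottom", "middle", "top"))
}
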