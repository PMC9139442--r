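#' Configuration for the synthetic pharmacogenomic cohort
#'
#' Describes a cohort in which each sample carries a latent drug-sensitivity
#' value on a standard-normal axis. A set of "up" genes is planted whose
#' log-expression increases with sensitivity, a disjoint set of "down" genes
#' decreases with it, and all remaining genes are uncorrelated noise. The
#' drug-response AUC (activity area, oriented so that higher means more
#' sensitive) is an affine function of the latent axis plus Gaussian noise,
#' clamped to [0, 1].
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (cell lines).
#' @param n_up,n_down Numbers of planted sensitivity- and
#'   resistance-associated genes; `n_up + n_down < n_genes`.
#' @param effect_size Slope (log2 units per latent SD) of planted genes on
#'   the latent axis.
#' @param noise_sd_expr SD of Gaussian noise added to every log-expression
#'   value.
#' @param noise_sd_auc SD of Gaussian noise added to the AUC before clamping.
#' @param auc_intercept,auc_slope Affine map from the latent axis to AUC.
#' @param library_size_range Length-2 integer vector; per-sample library
#'   sizes are drawn uniformly from this range.
#' @param gene_length_range Length-2 integer vector of gene lengths (bp).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   cohorts.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_genes = 1000,
                             n_samples = 60,
                             n_up = 20,
                             n_down = 20,
                             effect_size = 1.5,
                             noise_sd_expr = 0.3,
                             noise_sd_auc = 0.05,
                             auc_intercept = 0.5,
                             auc_slope = 0.15,
                             library_size_range = c(5e5, 1e6),
                             gene_length_range = c(200, 5000),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              effect_size = effect_size, noise_sd_expr = noise_sd_expr,
              noise_sd_auc = noise_sd_auc, auc_intercept = auc_intercept,
              auc_slope = auc_slope,
              library_size_range = as.numeric(library_size_range),
              gene_length_range = as.numeric(gene_length_range),
              seed = as.integer(seed))
  if (cfg$n_genes < 2 || cfg$n_samples < 1)
    stop("n_genes must be >= 2 and n_samples >= 1")
  if (cfg$n_up < 0 || cfg$n_down < 0)
    stop("n_up and n_down must be non-negative")
  if (cfg$n_up + cfg$n_down >= cfg$n_genes)
    stop("n_up + n_down must be smaller than n_genes")
  if (cfg$noise_sd_expr < 0 || cfg$noise_sd_auc < 0)
    stop("noise SDs must be non-negative")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("library_size_range must be an increasing pair of positive numbers")
  if (length(cfg$gene_length_range) != 2 || any(cfg$gene_length_range <= 0) ||
      diff(cfg$gene_length_range) < 0)
    stop("gene_length_range must be an increasing pair of positive numbers")
  structure(cfg, class = "synthetic_config")
}

# internal: deterministic gene-role assignment shared by generate_cohort and
# generate_batch_shifted_pair so replicate cohorts plant the same programs.
# Uses its own RNG stream derived from the config seed.
gene_roles <- function(config) {
  ids <- sprintf("gene%04d", seq_len(config$n_genes))
  roles <- withr::with_seed(config$seed, {
    baseline <- stats::runif(config$n_genes, min = 2, max = 8)
    lengths <- round(stats::runif(config$n_genes,
                                  config$gene_length_range[1],
                                  config$gene_length_range[2]))
    planted <- sample.int(config$n_genes, config$n_up + config$n_down)
    list(baseline = baseline, lengths = lengths,
         up = planted[seq_len(config$n_up)],
         down = planted[config$n_up + seq_len(config$n_down)])
  })
  list(gene_ids = ids, baseline = stats::setNames(roles$baseline, ids),
       gene_lengths = stats::setNames(roles$lengths, ids),
       up_idx = roles$up, down_idx = roles$down)
}

# internal: simulate log-expression for a cohort given roles and a latent
# sensitivity vector
simulate_expression <- function(config, roles, latent) {
  n_g <- config$n_genes
  n_s <- length(latent)
  expr <- matrix(roles$baseline, nrow = n_g, ncol = n_s)
  if (config$n_up > 0)
    expr[roles$up_idx, ] <- expr[roles$up_idx, , drop = FALSE] +
      config$effect_size * matrix(latent, config$n_up, n_s, byrow = TRUE)
  if (config$n_down > 0)
    expr[roles$down_idx, ] <- expr[roles$down_idx, , drop = FALSE] -
      config$effect_size * matrix(latent, config$n_down, n_s, byrow = TRUE)
  expr + matrix(stats::rnorm(n_g * n_s, sd = config$noise_sd_expr), n_g, n_s)
}

# internal: expression (log2 RPKM scale) -> Poisson counts at given library
# sizes; relative expected counts proportional to RPKM x gene length, scaled
# so each sample's expected total equals its library size
expression_to_counts <- function(expr, gene_lengths, lib_sizes) {
  rpkm <- pmax(2^expr - 1, 0)
  rel <- rpkm * gene_lengths
  expected <- sweep(rel, 2, colSums(rel), "/")
  expected <- sweep(expected, 2, lib_sizes, "*")
  counts <- matrix(stats::rpois(length(expected), lambda = expected),
                   nrow = nrow(expr), dimnames = dimnames(expr))
  counts
}

#' Generate a synthetic pharmacogenomic cohort
#'
#' Produces matched counts, log-expression, drug response and ground truth
#' for one cohort under a [synthetic_config()]. Per-sample latent
#' sensitivity values are standard normal; AUC is
#' `clamp(auc_intercept + auc_slope * s + noise, 0, 1)`; planted up/down
#' genes move with `+/- effect_size * s`; counts are Poisson draws whose
#' per-sample expected totals equal the drawn library sizes, so converting
#' counts back to log RPKM recovers the expression matrix up to Poisson
#' noise and a per-sample constant.
#'
#' @param config A [synthetic_config()].
#' @param drug_id Column name used for the drug in the response table.
#' @return A list with elements:
#' \describe{
#'   \item{counts}{[count_matrix] of Poisson counts with gene lengths.}
#'   \item{expr}{log-expression matrix (genes x samples).}
#'   \item{response}{data.frame with `sample_id` and one AUC column per drug
#'     (here a single column named by `drug_id`).}
#'   \item{truth}{list: `up_genes`, `down_genes` (disjoint id sets of sizes
#'     `n_up`, `n_down`) and `latent` (per-sample latent sensitivity).}
#' }
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_genes = 50, n_samples = 10,
#'                                            n_up = 3, n_down = 3, seed = 7))
#' dim(cohort$expr)
#' @export
generate_cohort <- function(config, drug_id = "drugA") {
  stopifnot(inherits(config, "synthetic_config"))
  roles <- gene_roles(config)
  out <- withr::with_seed(config$seed + 1L, {
    latent <- stats::rnorm(config$n_samples)
    expr <- simulate_expression(config, roles, latent)
    auc <- config$auc_intercept + config$auc_slope * latent +
      stats::rnorm(config$n_samples, sd = config$noise_sd_auc)
    auc <- pmin(pmax(auc, 0), 1)
    lib <- round(stats::runif(config$n_samples,
                              config$library_size_range[1],
                              config$library_size_range[2]))
    list(latent = latent, expr = expr, auc = auc, lib = lib)
  })
  sample_ids <- sprintf("sample%03d", seq_len(config$n_samples))
  dimnames(out$expr) <- list(roles$gene_ids, sample_ids)
  counts <- withr::with_seed(config$seed + 2L,
                       expression_to_counts(out$expr, roles$gene_lengths,
                                            out$lib))
  response <- data.frame(sample_id = sample_ids, auc = out$auc,
                         stringsAsFactors = FALSE)
  names(response)[2] <- drug_id
  list(counts = count_matrix(counts, roles$gene_lengths),
       expr = out$expr,
       response = response,
       truth = list(up_genes = roles$gene_ids[roles$up_idx],
                    down_genes = roles$gene_ids[roles$down_idx],
                    latent = stats::setNames(out$latent, sample_ids)))
}

#' Generate a batch-shifted replicate cohort pair
#'
#' Emulates the cross-dataset scoring problem: the same cohort (shared latent
#' sensitivity axis and planted gene programs) profiled twice, where the
#' second dataset suffers a location/scale distortion of its background
#' genes, plus a small panel of stably expressed anchor genes present in
#' both. Planted signature genes and the anchor panel keep their calibration
#' across datasets — the premise of stable-gene-anchored scoring — while the
#' shifted background displaces within-sample ranks, so rank-versus-all
#' scores (singscore) drift between datasets while anchored scores
#' (stingscore) remain comparable.
#'
#' Anchor genes are chosen from the background, re-assigned near-constant
#' baselines evenly spread over the expression range (log-scale SD 0.01),
#' and exempt from the distortion.
#'
#' @param config A [synthetic_config()].
#' @param shift Additive log-expression offset applied to background genes of
#'   the second dataset.
#' @param scale Multiplicative factor (> 0) applied to background genes of
#'   the second dataset (about the background mean, so `scale` alone does not
#'   move column means).
#' @param n_stable Number of stable anchor genes (< `n_genes`).
#' @return List with `expr1`, `expr2` (matched columns), `stable_genes`
#'   (anchor gene ids) and `truth` as in [generate_cohort()].
#' @export
generate_batch_shifted_pair <- function(config, shift = 0, scale = 1,
                                        n_stable = 5) {
  stopifnot(inherits(config, "synthetic_config"))
  if (scale <= 0) stop("`scale` must be strictly positive")
  if (n_stable >= config$n_genes)
    stop("`n_stable` must be smaller than n_genes")
  roles <- gene_roles(config)
  planted <- c(roles$up_idx, roles$down_idx)
  stable_idx <- withr::with_seed(config$seed + 3L, {
    pool <- setdiff(seq_len(config$n_genes), planted)
    sample(pool, n_stable)
  })
  # anchors at evenly spaced baselines across the expression range
  roles$baseline[stable_idx] <- seq(3, 7, length.out = n_stable)

  latent <- withr::with_seed(config$seed + 1L, stats::rnorm(config$n_samples))
  sample_ids <- sprintf("sample%03d", seq_len(config$n_samples))

  make_expr <- function(sub_seed) {
    e <- withr::with_seed(sub_seed, {
      m <- simulate_expression(config, roles, latent)
      m[stable_idx, ] <- roles$baseline[stable_idx] +
        stats::rnorm(n_stable * config$n_samples, sd = 0.01)
      m
    })
    dimnames(e) <- list(roles$gene_ids, sample_ids)
    e
  }
  expr1 <- make_expr(config$seed + 4L)
  expr2 <- make_expr(config$seed + 5L)

  background <- setdiff(seq_len(config$n_genes), c(planted, stable_idx))
  centre <- mean(expr2[background, ])
  expr2[background, ] <- (expr2[background, ] - centre) * scale +
    centre + shift

  list(expr1 = expr1, expr2 = expr2,
       stable_genes = roles$gene_ids[stable_idx],
       truth = list(up_genes = roles$gene_ids[roles$up_idx],
                    down_genes = roles$gene_ids[roles$down_idx],
                    latent = stats::setNames(latent, sample_ids)))
}

#' Simulate xenograft tumor growth curves
#'
#' Per-mouse tumor-volume time series measured twice weekly. Tumors grow
#' exponentially from engraftment; treatment starts (first drug injection)
#' at the first measurement at or above 200 mm3. Responder tumors then
#' shrink for about three weeks before regrowing; resistant tumors keep
#' growing monotonically.
#'
#' @param n_mice Number of mice (>= 1).
#' @param responder Logical; if `TRUE` tumors regress below the
#'   first-injection volume after treatment.
#' @param seed Integer seed.
#' @param model_id Xenograft model identifier stamped on each curve.
#' @param arm Treatment arm label (`"treated"` or `"control"`).
#' @param decay_rate Mean per-day shrink rate of responder tumors during the
#'   treatment window; deeper responders (more drug-sensitive models) decay
#'   faster and reach lower NTR. Ignored for resistant curves.
#' @return List of [growth_curve] objects, one per mouse.
#' @seealso [normalized_tumor_response()]
#' @export
generate_growth_curves <- function(n_mice, responder, seed = 1L,
                                   model_id = "PDX", arm = "treated",
                                   decay_rate = 0.07) {
  if (n_mice < 1) stop("n_mice must be >= 1")
  days <- sort(unique(c(seq(0, 70, by = 7), seq(4, 70, by = 7))))
  withr::with_seed(seed, {
    lapply(seq_len(n_mice), function(i) {
      v0 <- stats::runif(1, 40, 70)
      g <- stats::rnorm(1, mean = 0.075, sd = 0.008)
      vol <- numeric(length(days))
      vol[1] <- v0
      inj_i <- NA_integer_
      for (j in 2:length(days)) {
        dt <- days[j] - days[j - 1]
        if (is.na(inj_i)) {
          rate <- abs(g + stats::rnorm(1, sd = 0.01))
          vol[j] <- vol[j - 1] * exp(rate * dt)
          if (vol[j] >= 200 && is.na(inj_i)) inj_i <- j
        } else if (responder && days[j] <= days[inj_i] + 21) {
          rate <- abs(stats::rnorm(1, mean = decay_rate, sd = 0.01))
          vol[j] <- vol[j - 1] * exp(-rate * dt)
        } else if (responder) {
          rate <- abs(stats::rnorm(1, mean = 0.03, sd = 0.005))
          vol[j] <- vol[j - 1] * exp(rate * dt)
        } else {
          rate <- abs(g + stats::rnorm(1, sd = 0.01))
          vol[j] <- vol[j - 1] * exp(rate * dt)
        }
      }
      if (is.na(inj_i)) inj_i <- length(days)  # unreachable at these rates
      growth_curve(mouse_id = sprintf("%s_m%02d", model_id, i),
                   model_id = model_id, arm = arm,
                   days = days, volumes = vol,
                   first_injection_day = days[inj_i])
    })
  })
}
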