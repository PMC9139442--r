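# Synthetic cohort generator: determinism, planted structure, batch pair,
# growth curves.

small_cfg <- function(...) {
  synthetic_config(n_genes = 200, n_samples = 30, n_up = 8, n_down = 8, ...)
}

test_that("identical configurations generate bit-identical cohorts", {
  a <- generate_cohort(small_cfg(seed = 7))
  b <- generate_cohort(small_cfg(seed = 7))
  expect_identical(a$expr, b$expr)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$response, b$response)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$expr, c2$expr))
})

test_that("truth record bookkeeping: disjoint planted sets of the right size", {
  co <- generate_cohort(synthetic_config(n_genes = 1000, n_samples = 20,
                                         n_up = 20, n_down = 20, seed = 2))
  expect_length(co$truth$up_genes, 20)
  expect_length(co$truth$down_genes, 20)
  expect_length(intersect(co$truth$up_genes, co$truth$down_genes), 0)
  expect_true(all(c(co$truth$up_genes, co$truth$down_genes) %in%
                    rownames(co$expr)))
  expect_length(co$truth$latent, 20)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_genes = 30, n_up = 20, n_down = 10),
               "smaller than n_genes")
  expect_error(synthetic_config(noise_sd_expr = -1), "non-negative")
  expect_error(synthetic_config(library_size_range = c(0, 10)), "positive")
})

test_that("AUC values are clamped to [0, 1]", {
  co <- generate_cohort(small_cfg(seed = 3, auc_slope = 2,
                                  noise_sd_auc = 0.5))
  expect_true(all(co$response$drugA >= 0 & co$response$drugA <= 1))
})

test_that("planted up genes out-correlate the null genes with AUC", {
  cfg <- synthetic_config(n_genes = 500, n_samples = 60, n_up = 10,
                          n_down = 10, effect_size = 1.5,
                          noise_sd_expr = 0.3, seed = 11)
  co <- generate_cohort(cfg)
  rho <- apply(co$expr, 1, oracle_spearman, co$response$drugA)
  null_genes <- setdiff(rownames(co$expr),
                        c(co$truth$up_genes, co$truth$down_genes))
  cutoff <- stats::quantile(rho[null_genes], 0.95)
  expect_true(all(rho[co$truth$up_genes] > cutoff))
  expect_true(all(rho[co$truth$down_genes] <
                    stats::quantile(rho[null_genes], 0.05)))
})

test_that("counts round-trip through log RPKM up to Poisson noise", {
  co <- generate_cohort(small_cfg(seed = 5))
  back <- counts_to_log_rpkm(co$counts)
  expect_gt(stats::cor(as.numeric(back), as.numeric(co$expr)), 0.97)
  # expected per-sample totals track the drawn library sizes
  expect_true(all(abs(library_sizes(co$counts) /
                        mean(library_sizes(co$counts)) - 1) < 0.6))
})

test_that("batch pair: identity distortion reproduces the cohort distribution", {
  cfg <- small_cfg(seed = 9)
  pair <- generate_batch_shifted_pair(cfg, shift = 0, scale = 1)
  expect_identical(dim(pair$expr1), dim(pair$expr2))
  expect_lt(abs(mean(pair$expr1) - mean(pair$expr2)), 0.05)
  expect_lt(abs(stats::sd(pair$expr1) - stats::sd(pair$expr2)), 0.05)
  # matched columns share the latent signal
  sig <- drug_signature("d", pair$truth$up_genes, pair$truth$down_genes)
  s1 <- score_matrix(pair$expr1, sig)$total_score
  s2 <- score_matrix(pair$expr2, sig)$total_score
  expect_gt(stats::cor(s1, s2, method = "spearman"), 0.9)
})

test_that("batch pair: shift moves second-dataset column means by about shift", {
  pair <- generate_batch_shifted_pair(small_cfg(seed = 9), shift = 5)
  d <- colMeans(pair$expr2) - colMeans(pair$expr1)
  expect_true(all(abs(d - 5) < 1))   # background is ~92% of genes here
})

test_that("batch pair: stable genes are near-constant in both datasets", {
  pair <- generate_batch_shifted_pair(small_cfg(seed = 9), shift = 5,
                                      n_stable = 5)
  expect_length(pair$stable_genes, 5)
  for (m in list(pair$expr1, pair$expr2)) {
    sds <- apply(m[pair$stable_genes, ], 1, stats::sd)
    expect_true(all(sds < 0.05))
  }
  expect_error(generate_batch_shifted_pair(small_cfg(), n_stable = 200),
               "smaller than n_genes")
  expect_error(generate_batch_shifted_pair(small_cfg(), scale = 0),
               "positive")
})

test_that("stingscore agrees across the batch pair while singscore drifts", {
  cfg <- synthetic_config(seed = 2)
  pair <- generate_batch_shifted_pair(cfg, shift = 5, scale = 1)
  sig <- drug_signature("d", pair$truth$up_genes, pair$truth$down_genes)
  st1 <- score_matrix(pair$expr1, sig, "stingscore", panel = pair$stable_genes)
  st2 <- score_matrix(pair$expr2, sig, "stingscore", panel = pair$stable_genes)
  expect_gte(stats::cor(st1$total_score, st2$total_score,
                        method = "spearman"), 0.9)
  # anchored score means stay aligned across datasets
  expect_lt(abs(mean(st1$total_score) - mean(st2$total_score)), 0.05)
  # the naive rank-versus-all score is displaced by the background shift
  ss1 <- score_matrix(pair$expr1, sig)
  ss2 <- score_matrix(pair$expr2, sig)
  expect_gt(abs(mean(ss2$up_score) - mean(ss1$up_score)), 0.2)
})

test_that("growth curves respect the responder/resistant contracts", {
  res <- generate_growth_curves(4, responder = FALSE, seed = 21)
  for (cv in res) {
    post <- cv$volumes[cv$days >= cv$first_injection_day]
    v_inj <- cv$volumes[cv$days == cv$first_injection_day]
    expect_true(all(post >= v_inj))
    expect_equal(normalized_tumor_response(cv), 1)
  }
  resp <- generate_growth_curves(4, responder = TRUE, seed = 22)
  for (cv in resp) {
    post <- cv$volumes[cv$days >= cv$first_injection_day]
    v_inj <- cv$volumes[cv$days == cv$first_injection_day]
    expect_lt(min(post), v_inj)
    expect_lt(normalized_tumor_response(cv), 1)
  }
  expect_identical(generate_growth_curves(3, TRUE, seed = 5),
                   generate_growth_curves(3, TRUE, seed = 5))
  expect_error(generate_growth_curves(0, TRUE), ">= 1")
})

test_that("null cohorts yield signatures an order of magnitude below planted ones", {
  cfg <- synthetic_config(n_genes = 500, n_samples = 60, n_up = 10,
                          n_down = 10, effect_size = 0, seed = 31)
  co <- generate_cohort(cfg)
  p <- signature_params(n_resamples = 100, seed = 32)
  freq <- resample_correlations(
    co$expr, stats::setNames(co$response$drugA, co$response$sample_id), p)
  sig <- suppressWarnings(derive_signature(freq, p, "null"))
  n_sel <- length(sig$up_genes) + length(sig$down_genes)
  # overlapping resamples keep a few lucky null genes in the tails, but the
  # selection stays far below the planted-signal regime (which recovers all
  # 20 planted genes under these settings)
  expect_lte(n_sel, 0.02 * cfg$n_genes)
})
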