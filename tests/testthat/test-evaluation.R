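# Agreement metrics, confidence tiers, drug similarity, stratification.

test_that("spearman_rho handles the canonical cases and matches its oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  for (i in 1:20) {
    d <- withr::with_seed(500 + i, {
      list(a = sample(1:5, 8, replace = TRUE),
           b = sample(1:5, 8, replace = TRUE))
    })
    if (stats::sd(d$a) == 0 || stats::sd(d$b) == 0) next
    expect_equal(spearman_rho(d$a, d$b), oracle_spearman(d$a, d$b),
                 tolerance = 1e-12)
  }
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("concordance index matches exhaustive enumeration", {
  expect_equal(concordance_index(1:6, 1:6), 1)
  expect_equal(concordance_index(6:1, 1:6), 0)
  expect_equal(concordance_index(c(1, 3, 2), c(1, 2, 3)), 2 / 3)
  for (i in 1:60) {
    d <- withr::with_seed(600 + i, {
      n <- sample(2:7, 1)
      list(p = sample(1:4, n, replace = TRUE),
           o = sample(1:4, n, replace = TRUE))
    })
    if (stats::sd(d$o) == 0) next
    expect_equal(concordance_index(d$p, d$o), oracle_ci(d$p, d$o),
                 tolerance = 1e-12)
  }
  expect_warning(out <- concordance_index(1:4, rep(2, 4)), "tied")
  expect_true(is.na(out))
})

test_that("concordance index agrees with survival::concordance", {
  skip_if_not_installed("survival")
  for (i in 1:10) {
    d <- withr::with_seed(700 + i,
      list(p = sample(1:6, 9, replace = TRUE),
           o = sample(1:6, 9, replace = TRUE)))
    if (stats::sd(d$o) == 0) next
    expect_equal(concordance_index(d$p, d$o),
                 unname(survival::concordance(d$o ~ d$p)$concordance),
                 tolerance = 1e-12)
  }
})

test_that("rank metrics are invariant under increasing transforms", {
  d <- withr::with_seed(9, list(p = stats::rnorm(25), o = stats::rnorm(25)))
  expect_equal(concordance_index(exp(d$p), d$o),
               concordance_index(d$p, d$o))
  expect_equal(spearman_rho(d$p, d$o^3 + d$o), spearman_rho(d$p, d$o))
})

test_that("CI of random permutations concentrates at one half", {
  cis <- withr::with_seed(12, {
    o <- 1:30
    replicate(200, concordance_index(sample(o), o))
  })
  expect_lt(abs(mean(cis) - 0.5), 0.02)
})

test_that("confidence tiers reproduce the published worked examples", {
  lapatinib <- data.frame(rho = c(0.68, 0.54, 0.5, 0.34, 0.26, 0.9))
  expect_identical(classify_confidence(lapatinib), "high")
  cisplatin <- data.frame(rho = c(0.37, 0.29))
  expect_identical(classify_confidence(cisplatin), "medium")
  expect_identical(classify_confidence(data.frame(rho = c(0, 0, 0))), "low")
  # CI can rescue a tier on its own
  expect_identical(classify_confidence(data.frame(rho = 0.1, ci = 0.7)),
                   "high")
  expect_identical(classify_confidence(data.frame(rho = 0.1, ci = 0.62)),
                   "medium")
  expect_identical(classify_confidence(data.frame(rho = 0.1, ci = NA)),
                   "low")
  expect_error(classify_confidence(data.frame()), "at least one")
})

test_that("confidence classification is monotone in rho", {
  tier_rank <- c(low = 1, medium = 2, high = 3)
  for (i in 1:30) {
    evals <- withr::with_seed(800 + i,
      data.frame(rho = stats::runif(3, -0.2, 0.6)))
    before <- tier_rank[classify_confidence(evals)]
    j <- withr::with_seed(900 + i, sample(3, 1))
    evals$rho[j] <- evals$rho[j] + 0.15
    after <- tier_rank[classify_confidence(evals)]
    expect_gte(after, before)
  }
})

test_that("drug similarity matrices are symmetric with unit diagonal", {
  auc <- withr::with_seed(15, {
    base <- stats::rnorm(20)
    data.frame(sample_id = sprintf("s%02d", 1:20),
               d1 = base + stats::rnorm(20, 0, 0.2),
               d2 = base + stats::rnorm(20, 0, 0.2),
               d3 = stats::rnorm(20))
  })
  sigs <- list(drug_signature("d1", c("a", "b", "c")),
               drug_signature("d2", c("b", "c", "d")),
               drug_signature("d3", c("x", "y")))
  sim <- drug_similarity(auc, sigs)
  expect_equal(diag(sim$response_rho), rep(1, 3), ignore_attr = TRUE)
  expect_identical(sim$response_rho, t(sim$response_rho))
  expect_identical(sim$response_p, t(sim$response_p))
  expect_true(sim$response_significant["d1", "d2"])  # shared latent driver
  expect_equal(sim$signature_jaccard["d1", "d2"], 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(diag(sim$signature_jaccard), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sim$signature_jaccard["d1", "d3"], 0)
})

test_that("signature Jaccard matches a set-arithmetic oracle", {
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:15) {
    ab <- withr::with_seed(1000 + i, list(a = sample(pool, 8),
                                          b = sample(pool, 12)))
    sigs <- list(drug_signature("A", ab$a), drug_signature("B", ab$b))
    auc <- data.frame(A = stats::rnorm(5), B = stats::rnorm(5))
    sim <- suppressWarnings(drug_similarity(auc, sigs))
    expect_equal(sim$signature_jaccard["A", "B"],
                 length(intersect(ab$a, ab$b)) / length(union(ab$a, ab$b)))
  }
})

test_that("pairs without shared coverage are reported missing", {
  auc <- data.frame(d1 = c(1, 2, 3, NA, NA, NA),
                    d2 = c(NA, NA, NA, 1, 2, 3))
  sim <- drug_similarity(auc)
  expect_true(is.na(sim$response_rho["d1", "d2"]))
  expect_error(drug_similarity(auc[, 1, drop = FALSE]), "at least 2")
})

test_that("separate-tail Jaccard distinguishes the two directions", {
  sigs <- list(drug_signature("A", up_genes = c("u1", "u2"),
                              down_genes = c("d1", "d2")),
               drug_signature("B", up_genes = c("u1", "u2"),
                              down_genes = c("x1", "x2")))
  auc <- data.frame(A = stats::rnorm(5), B = stats::rnorm(5))
  sim <- suppressWarnings(drug_similarity(auc, sigs, separate_tails = TRUE))
  expect_equal(sim$signature_jaccard$up["A", "B"], 1)
  expect_equal(sim$signature_jaccard$down["A", "B"], 0)
})

test_that("score stratification cuts the stated extreme deciles", {
  tiers <- stratify_by_score(1:100)
  expect_equal(sum(tiers == "bottom"), 10)
  expect_equal(sum(tiers == "top"), 10)
  expect_equal(sum(tiers == "middle"), 80)
  expect_length(tiers, 100)                    # tiers partition the samples
  expect_warning(t2 <- stratify_by_score(rep(1, 20)), "degenerate")
  expect_equal(length(unique(t2)), 1)
  expect_error(stratify_by_score(1:10, 0.9, 0.1), "below")
})
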