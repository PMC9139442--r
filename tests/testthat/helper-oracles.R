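# Independent first-principles oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check:
# ranks are computed by explicit pairwise comparison counting, the
# concordance index by exhaustive pair enumeration, and Spearman's rho by
# rank-then-Pearson.

# rank by comparison counting (average ranks for ties)
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, 0)
}

# bidirectional rank score from first principles
oracle_singscore <- function(profile, up, down) {
  n <- length(profile)
  r <- oracle_ranks(profile)
  comp <- function(ranks, set) {
    m <- length(set)
    if (m == 0) return(NA_real_)
    rbar <- mean(ranks[names(profile) %in% set])
    r_min <- mean(seq_len(m))                 # smallest possible mean rank
    r_max <- mean(seq(n - m + 1, n))          # largest possible mean rank
    (rbar - r_min) / (r_max - r_min) - 0.5
  }
  up_s <- comp(r, up)
  down_s <- comp(n - r + 1, down)
  list(up = up_s, down = down_s, total = sum(c(up_s, down_s), na.rm = TRUE))
}

# concordance index by exhaustive pair enumeration
oracle_ci <- function(predicted, observed) {
  num <- 0
  den <- 0
  n <- length(predicted)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (observed[i] == observed[j]) next
      den <- den + 1
      if (predicted[i] == predicted[j]) {
        num <- num + 0.5
      } else if ((predicted[i] < predicted[j]) ==
                 (observed[i] < observed[j])) {
        num <- num + 1
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Spearman rho as Pearson correlation of comparison-count ranks
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small random expression matrix with dimnames
random_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n_samples))))
  })
}
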