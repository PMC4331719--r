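# Independent brute-force oracles used to pin down the analytic operations.
# These deliberately re-derive each quantity from first principles and share
# no code with the package internals.

# Exhaustive search over every (feature, midpoint threshold) pair, with the
# documented tie-break: lower weighted impurity, then lower feature index,
# then lower threshold. Candidate order is normalized by sorting.
oracle_best_split <- function(x, y, candidates) {
  y <- factor(y)
  eps <- 1e-12
  best <- NULL
  for (f in sort(candidates)) {
    v <- sort(unique(x[, f]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      left <- x[, f] <= thr
      lc <- table(y[left]); rc <- table(y[!left])
      n1 <- sum(lc); n2 <- sum(rc); n <- n1 + n2
      g <- (n1 / n) * (1 - sum((lc / n1)^2)) +
           (n2 / n) * (1 - sum((rc / n2)^2))
      if (is.null(best) || g < best$gini - eps) {
        best <- list(feature = f, threshold = thr, gini = g)
      }
    }
  }
  best
}

# Full enumeration of the one-sided rank-sum null distribution: under H0 all
# C(m+n, m) assignments of ranks to x are equally likely.
oracle_wilcoxon_greater <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  all_w <- apply(utils::combn(m + n, m), 2, function(ix) sum(r[ix]))
  mean(all_w >= w_obs)
}

# Textbook Pearson statistic by direct summation of (O - E)^2 / E.
oracle_chi2_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Small random genotype dataset for property tests.
random_dataset <- function(n = 8, m = 4, seed = NULL, kind = "genotype") {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    labels <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(labels)) == 2) break
  }
  vals <- if (kind == "genotype")
    matrix(sample(0:2, n * m, replace = TRUE), n, m)
  else matrix(rnorm(n * m), n, m)
  labeled_dataset(vals, labels,
                  feature_ids = sprintf("f%02d", seq_len(m)),
                  sample_ids = sprintf("s%02d", seq_len(n)),
                  feature_kind = kind)
}
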