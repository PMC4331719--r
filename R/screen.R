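#' Extend a dataset with shadow features
#'
#' Appends, for each of the M original features, a shadow copy obtained by an
#' independent row permutation of that column. A shadow keeps its source's
#' marginal distribution but has no association with the class labels, so
#' shadow importance scores calibrate what "noise" looks like for this data.
#' Shadow IDs are the original IDs with the reserved suffix `"__shadow"`.
#'
#' @param d a [labeled_dataset()].
#' @param seed integer seed for the permutations.
#' @return a `labeled_dataset` with 2M features (originals first, shadows
#'   after, in source order) and unchanged labels.
#' @export
make_shadow_extended <- function(d, seed = 1) {
  validate_dataset(d)
  m <- ncol(d$values)
  shadows <- with_seed(seed, {
    apply(d$values, 2, sample)
  })
  labeled_dataset(cbind(d$values, shadows), d$labels,
                  feature_ids = c(d$feature_ids,
                                  paste0(d$feature_ids, "__shadow")),
                  sample_ids = d$sample_ids, feature_kind = d$feature_kind)
}

#' Replicated importance scores against shadow features
#'
#' For each of `R` replicates: a fresh shadow extension is generated (new
#' permutations), a forest of `K_screen` trees with plain uniform subspace
#' sampling of size `mtry_screen` over all 2M columns is fitted, and the raw
#' Gini importances are read off. The replicate's original-feature scores
#' form one row of `real_scores`; the maximum over its shadow scores is one
#' element of the comparison sample `shadow_max`.
#'
#' @param d a [labeled_dataset()].
#' @param R number of replicates (>= 2).
#' @param K_screen trees per screening forest.
#' @param mtry_screen per-node subspace size for the screening forests;
#'   default `max(2, floor(0.1 * M))`.
#' @param n_min minimum node size.
#' @param seed integer seed; replicate r's permutations and forest derive
#'   deterministically from it.
#' @return an object of class `importance_replicates`: `real_scores` (R by M,
#'   columns named by feature), `shadow_max` (length R), and the screen
#'   parameters.
#' @export
importance_replicates <- function(d, R = 30, K_screen = 50,
                                  mtry_screen = NULL, n_min = 1, seed = 1) {
  validate_dataset(d)
  stopifnot(R >= 2, K_screen >= 1)
  m <- ncol(d$values)
  if (is.null(mtry_screen)) mtry_screen <- max(2, floor(0.1 * m))
  mtry_screen <- as.integer(min(mtry_screen, 2L * m))
  seeds <- derive_seeds(seed, 2L * R)
  real <- matrix(0, nrow = R, ncol = m,
                 dimnames = list(NULL, d$feature_ids))
  shadow_max <- numeric(R)
  for (r in seq_len(R)) {
    ext <- make_shadow_extended(d, seed = seeds[2 * r - 1])
    f <- fit_forest(ext, K = K_screen,
                    sampler = uniform_sampler(seq_len(2L * m), mtry_screen),
                    n_min = n_min, seed = seeds[2 * r])
    imp <- raw_importance(f)
    real[r, ] <- imp[seq_len(m)]
    shadow_max[r] <- max(imp[(m + 1):(2 * m)])
  }
  structure(list(real_scores = real, shadow_max = shadow_max, R = R,
                 K_screen = as.integer(K_screen),
                 mtry_screen = mtry_screen, n_min = as.integer(n_min),
                 seed = as.integer(seed)),
            class = "importance_replicates")
}

#' One-sided Wilcoxon rank-sum p-value
#'
#' Two-sample rank-sum test of the alternative "x is stochastically greater
#' than y". The p-value is exact (full enumeration of rank assignments) when
#' the combined sample has at most 12 observations and no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. In the screen, `x` holds a feature's R replicate importance scores
#' and `y` the R shadow maxima.
#'
#' @param x,y nonempty numeric vectors.
#' @return p-value in `[0, 1]`.
#' @examples
#' wilcoxon_greater_pvalue(c(5, 6, 7), c(1, 2, 3))  # 0.05
#' @export
wilcoxon_greater_pvalue <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1) return(1)  # fully tied: no evidence
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Stage 1: Wilcoxon screen against the shadow maxima
#'
#' Each feature's replicate importance scores are compared against the
#' shadow-maximum sample with [wilcoxon_greater_pvalue()]. Features whose
#' p-value exceeds `theta` are considered irrelevant and removed; the
#' survivors form the informative set. A feature with p-value exactly
#' `theta` is retained.
#'
#' @param rep an [importance_replicates()] result.
#' @param theta significance threshold in (0, 1); default 0.05.
#' @return list with `wilcoxon_p` (named, length M) and `informative`
#'   (integer indices of the surviving features).
#' @export
stage1_filter <- function(rep, theta = 0.05) {
  stopifnot(inherits(rep, "importance_replicates"), theta > 0, theta < 1)
  p <- apply(rep$real_scores, 2, wilcoxon_greater_pvalue, y = rep$shadow_max)
  list(wilcoxon_p = p, informative = unname(which(p <= theta)))
}

#' Chi-squared association between one feature and the class labels
#'
#' Pearson chi-squared statistic (no continuity correction) on the
#' contingency table of feature categories by classes. Genotype categories
#' are the observed dosage values; continuous features are first discretized
#' into tertiles. Zero-margin categories are dropped. A feature that is
#' constant (or collapses to one category) has statistic 0 and p-value 1.
#'
#' @param feature_column numeric vector.
#' @param labels class labels (>= 2 classes present).
#' @param feature_kind `"genotype"` (categories = observed values) or
#'   `"continuous"` (tertile discretization).
#' @return list with `statistic` and `p.value`.
#' @export
chi2_association <- function(feature_column, labels,
                             feature_kind = c("genotype", "continuous")) {
  feature_kind <- match.arg(feature_kind)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need >= 2 classes present")
  x <- feature_column
  if (feature_kind == "continuous") {
    br <- unique(stats::quantile(x, c(0, 1/3, 2/3, 1)))
    if (length(br) < 2) x <- rep(1, length(x))
    else x <- cut(x, breaks = br, include.lowest = TRUE)
  }
  tab <- table(x, droplevels(labels))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, p.value = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}

#' Stage 2: partition informative features by association strength
#'
#' Applies [chi2_association()] to every stage-1 survivor and splits the
#' informative set into the highly informative group (p-value <= `alpha`)
#' and the weakly informative group (the rest).
#'
#' @param d the training [labeled_dataset()].
#' @param informative integer indices of the stage-1 survivors (nonempty).
#' @param alpha chi-squared threshold; default 0.05.
#' @return list with `chi2_p` (named p-values over the informative set),
#'   `strong` and `weak` (disjoint integer index sets whose union is
#'   `informative`).
#' @export
stage2_partition <- function(d, informative, alpha = 0.05) {
  validate_dataset(d)
  if (length(informative) == 0) stop("informative feature set is empty")
  p <- vapply(informative, function(f)
    chi2_association(d$values[, f], d$labels, d$feature_kind)$p.value,
    numeric(1))
  names(p) <- d$feature_ids[informative]
  list(chi2_p = p,
       strong = informative[p <= alpha],
       weak = informative[p > alpha])
}

#' Subspace sizes proportional to the strong/weak group sizes
#'
#' Splits a total per-node subspace size `mtry` between the two groups in
#' proportion to their sizes:
#' \eqn{mtry_s = \lfloor mtry \cdot |X_s| / (|X_s| + |X_w|) \rfloor},
#' raised to 1 whenever the strong group is nonempty (so every node's
#' subspace contains a strongly informative feature), with
#' \eqn{mtry_w = mtry - mtry_s}; each size is capped at its group size, and a
#' missing group gets 0 (the other then receives all of `mtry`).
#'
#' @param mtry total subspace size (>= 2 when both groups are nonempty).
#' @param n_strong,n_weak group sizes, not both 0.
#' @return list with integer `mtry_s` and `mtry_w`.
#' @examples
#' subspace_sizes(10, 30, 70)  # 3 and 7
#' @export
subspace_sizes <- function(mtry, n_strong, n_weak) {
  if (n_strong + n_weak < 1) stop("both feature groups are empty")
  if (n_strong > 0 && n_weak > 0 && mtry < 2)
    stop("mtry must be >= 2 when both groups are nonempty")
  if (n_strong == 0) {
    ms <- 0L
    mw <- as.integer(min(mtry, n_weak))
  } else if (n_weak == 0) {
    ms <- as.integer(min(mtry, n_strong))
    mw <- 0L
  } else {
    ms <- max(1L, as.integer(floor(mtry * n_strong / (n_strong + n_weak))))
    ms <- min(ms, as.integer(n_strong))
    mw <- min(as.integer(mtry) - ms, as.integer(n_weak))
  }
  list(mtry_s = ms, mtry_w = mw)
}

#' Run the full two-stage screen
#'
#' Convenience wrapper executing [importance_replicates()],
#' [stage1_filter()] and [stage2_partition()] on a training set.
#'
#' @param d a [labeled_dataset()].
#' @param R,K_screen,mtry_screen,n_min,seed see [importance_replicates()].
#' @param theta stage-1 Wilcoxon threshold.
#' @param alpha stage-2 chi-squared threshold.
#' @return an object of class `screen_result` with `wilcoxon_p`, `theta`,
#'   `informative`, `chi2_p`, `strong`, `weak`, `alpha`, `mean_importance`
#'   (per-feature mean of the replicate scores, used for ranking) and
#'   `feature_ids`.
#' @export
screen_features <- function(d, R = 30, K_screen = 50, mtry_screen = NULL,
                            theta = 0.05, alpha = 0.05, n_min = 1, seed = 1) {
  rep <- importance_replicates(d, R = R, K_screen = K_screen,
                               mtry_screen = mtry_screen, n_min = n_min,
                               seed = seed)
  s1 <- stage1_filter(rep, theta)
  if (length(s1$informative) == 0) {
    res <- list(wilcoxon_p = s1$wilcoxon_p, theta = theta,
                informative = integer(0), chi2_p = numeric(0),
                strong = integer(0), weak = integer(0), alpha = alpha,
                mean_importance = colMeans(rep$real_scores),
                feature_ids = d$feature_ids)
    return(structure(res, class = "screen_result"))
  }
  s2 <- stage2_partition(d, s1$informative, alpha)
  structure(list(wilcoxon_p = s1$wilcoxon_p, theta = theta,
                 informative = s1$informative, chi2_p = s2$chi2_p,
                 strong = s2$strong, weak = s2$weak, alpha = alpha,
                 mean_importance = colMeans(rep$real_scores),
                 feature_ids = d$feature_ids),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: ", length(x$wilcoxon_p), " features screened at theta=",
      x$theta, "\n  informative: ", length(x$informative),
      " (strong ", length(x$strong), ", weak ", length(x$weak),
      " at alpha=", x$alpha, ")\n", sep = "")
  invisible(x)
}
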