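#' Vote-based test accuracy
#'
#' \deqn{Acc = \frac{1}{N_t} \sum_i I(Q(x_i, y_i) - \max_{j \ne y_i}
#' Q(x_i, j) > 0),}
#' the fraction of samples whose true class strictly out-votes every other
#' class. A vote tie between the true class and another counts as an error
#' (the inequality is strict). Rows with denominator 0 (no voting trees, a
#' possibility for out-of-bag votes with few trees) are excluded, with a
#' message stating how many.
#'
#' @param vm a `vote_matrix` (see [votes()]).
#' @param true_labels labels aligned with the rows of `vm`.
#' @return accuracy in `[0, 1]`.
#' @export
test_accuracy <- function(vm, true_labels) {
  stopifnot(inherits(vm, "vote_matrix"))
  y <- match(as.character(true_labels), vm$label_order)
  if (anyNA(y)) stop("labels outside the vote matrix's label order")
  if (length(y) != nrow(vm$counts)) stop("labels do not align with votes")
  keep <- vm$denominator > 0
  if (any(!keep))
    message(sum(!keep), " sample(s) with no voting trees excluded")
  if (!any(keep)) stop("no samples with voting trees")
  q <- vm$counts[keep, , drop = FALSE]
  yk <- y[keep]
  own <- q[cbind(seq_len(nrow(q)), yk)]
  other <- vapply(seq_len(nrow(q)), function(i) max(q[i, -yk[i]]), numeric(1))
  mean(own - other > 0)
}

#' Rank-based AUC for binary classification
#'
#' Mann-Whitney form of the area under the ROC curve: the probability that a
#' random positive-class sample scores above a random negative-class sample,
#' with ties contributing 1/2.
#'
#' @param scores numeric scores (here: positive-class vote fractions).
#' @param labels binary labels aligned with `scores`.
#' @param positive the label treated as positive; default the first level in
#'   canonical (sorted) order.
#' @return AUC in `[0, 1]`.
#' @examples
#' binary_auc(c(0.9, 0.4, 0.6), c("case", "control", "case"), "case")  # 1
#' @export
binary_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stop("AUC requires exactly 2 classes present")
  if (is.null(positive)) positive <- levels(labels)[1]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-bag prediction margins
#'
#' For each sample, the margin is the vote-fraction lead of the true class
#' over the strongest other class:
#' \deqn{mr(x, y) = Q(x, y)/den - \max_{j \ne y} Q(x, j)/den \in [-1, 1].}
#' Samples with denominator 0 get `NA` (excluded, with a message).
#'
#' @param vm a `vote_matrix`, typically out-of-bag votes.
#' @param true_labels labels aligned with the rows of `vm`.
#' @return numeric vector of margins (NA where undefined).
#' @export
margins <- function(vm, true_labels) {
  stopifnot(inherits(vm, "vote_matrix"))
  y <- match(as.character(true_labels), vm$label_order)
  if (anyNA(y)) stop("labels outside the vote matrix's label order")
  n <- nrow(vm$counts)
  out <- rep(NA_real_, n)
  keep <- vm$denominator > 0
  if (any(!keep))
    message(sum(!keep), " sample(s) never out-of-bag excluded from margins")
  for (i in which(keep)) {
    q <- vm$counts[i, ] / vm$denominator[i]
    out[i] <- q[y[i]] - max(q[-y[i]])
  }
  out
}

#' Forest strength, correlation and the c/s^2 error bound
#'
#' Breiman's out-of-bag diagnostics. Strength `s` is the mean margin. The
#' mean tree correlation is estimated as
#' \deqn{\bar\rho = \mathrm{var}(mr) / (\overline{sd_k})^2,} where for tree k
#' over its out-of-bag samples \eqn{p_{1k}} is the fraction predicted
#' correctly, \eqn{p_{2k}} the fraction predicted as the sample's most-voted
#' wrong class \eqn{\hat j(x, y)}, and
#' \eqn{sd_k = \sqrt{p_{1k} + p_{2k} + (p_{1k} - p_{2k})^2}}. The
#' generalization-error bound is \eqn{c/s^2 = \bar\rho / s^2}, defined (and
#' returned non-NA) only when `s > 0`; lower is better. `var(mr)` is the
#' population variance of the margins.
#'
#' @param oob_votes out-of-bag `vote_matrix` of the training samples.
#' @param true_labels training labels.
#' @param tree_preds N-by-K matrix of per-tree predicted labels with `NA`
#'   wherever a sample was in-bag for the tree.
#' @return list with `strength`, `correlation`, `cs2` and `margins`.
#' @export
strength_correlation <- function(oob_votes, true_labels, tree_preds) {
  stopifnot(inherits(oob_votes, "vote_matrix"))
  lab <- oob_votes$label_order
  y <- match(as.character(true_labels), lab)
  mr <- margins(oob_votes, true_labels)
  keep <- !is.na(mr)
  if (sum(keep) < 2) stop("need at least 2 samples with out-of-bag votes")
  s <- mean(mr[keep])
  varmr <- mean((mr[keep] - s)^2)
  # per-sample most-voted wrong class; ties -> earliest in canonical order
  jhat <- integer(length(y))
  for (i in which(keep)) {
    q <- oob_votes$counts[i, ]
    q[y[i]] <- -1L
    jhat[i] <- which.max(q)
  }
  pr <- matrix(match(as.character(tree_preds), lab), nrow = nrow(tree_preds))
  K <- ncol(pr)
  sdk <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- which(!is.na(pr[, k]) & keep)
    if (length(idx) == 0) next
    p1 <- mean(pr[idx, k] == y[idx])
    p2 <- mean(pr[idx, k] == jhat[idx])
    sdk[k] <- sqrt(p1 + p2 + (p1 - p2)^2)
  }
  if (all(is.na(sdk))) stop("no tree has out-of-bag samples")
  msd <- mean(sdk, na.rm = TRUE)
  rho <- if (varmr == 0) 0 else varmr / msd^2
  cs2 <- if (s > 0) rho / s^2 else NA_real_
  list(strength = s, correlation = rho, cs2 = cs2, margins = mr)
}

#' Out-of-bag diagnostics of a fitted forest
#'
#' Computes the out-of-bag vote matrix on the forest's own training data and
#' derives strength, correlation, the c/s^2 bound, out-of-bag accuracy and
#' (for binary problems) out-of-bag AUC.
#'
#' @param forest a `tsrf_forest` (e.g. `model$forest` of a [fit_tsrf()]
#'   fit).
#' @param positive positive class for the AUC (default: first label in
#'   canonical order).
#' @return list with `strength`, `correlation`, `cs2`, `margins`,
#'   `accuracy`, and `auc` (NA unless binary).
#' @export
forest_diagnostics <- function(forest, positive = NULL) {
  stopifnot(inherits(forest, "tsrf_forest"))
  vm <- votes(forest, oob_only = TRUE)
  y <- forest$train_labels
  preds <- tree_predictions(forest, forest$train_values)
  lab <- matrix(forest$label_order[preds], nrow = nrow(preds))
  for (k in seq_along(forest$oob)) {
    inbag <- setdiff(seq_len(nrow(preds)), forest$oob[[k]])
    lab[inbag, k] <- NA
  }
  sc <- strength_correlation(vm, y, lab)
  keep <- vm$denominator > 0
  acc <- suppressMessages(test_accuracy(vm, y))
  auc <- NA_real_
  if (length(forest$label_order) == 2) {
    if (is.null(positive)) positive <- forest$label_order[1]
    fr <- vm$counts[keep, positive] / vm$denominator[keep]
    auc <- binary_auc(fr, y[keep], positive)
  }
  c(sc, list(accuracy = acc, auc = auc))
}

#' Stratified k-fold cross-validation of ts-RF against a plain forest
#'
#' Splits the samples into k folds preserving class proportions (per-fold
#' class counts within one sample of the global proportions). Within each
#' fold the full two-stage screen is re-run on the training portion only, so
#' no selection information leaks from a test fold into its model. The plain
#' random-forest baseline shares the tree engine and uses a uniform subspace
#' of size `floor(log2(M) + 1)` over all features (the classical default).
#'
#' @param d a [labeled_dataset()]; every class needs at least `k` members.
#' @param k number of folds (>= 2).
#' @param params a [tsrf_params()]; the per-fold fits derive their seeds from
#'   `seed` below, not from `params$seed`.
#' @param seed integer seed for fold assignment and all fold fits.
#' @param baseline also fit the plain-RF baseline on each fold.
#' @param baseline_mtry baseline subspace size; default
#'   `floor(log2(M) + 1)`.
#' @return data.frame with one row per (fold, model): columns `fold`,
#'   `model` (`"ts-RF"` / `"RF"`), `accuracy`, `auc`, `strength`,
#'   `correlation`, `cs2`; plus attribute `"folds"` holding the assignment.
#' @export
kfold_cv <- function(d, k = 5, params = tsrf_params(), seed = 1,
                     baseline = TRUE, baseline_mtry = NULL) {
  validate_dataset(d)
  stopifnot(k >= 2)
  y <- d$labels
  if (any(table(y) < k))
    stop("every class needs at least k = ", k, " members")
  n <- length(y)
  m <- ncol(d$values)
  if (is.null(baseline_mtry)) baseline_mtry <- max(1, floor(log2(m) + 1))
  fold <- integer(n)
  seeds <- derive_seeds(seed, 1 + 2 * k)
  with_seed(seeds[1], {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  subset_ds <- function(rows) {
    labeled_dataset(d$values[rows, , drop = FALSE], y[rows],
                    feature_ids = d$feature_ids,
                    sample_ids = d$sample_ids[rows],
                    feature_kind = d$feature_kind)
  }
  rows <- list()
  for (f in seq_len(k)) {
    tr <- subset_ds(fold != f)
    te <- subset_ds(fold == f)
    pos <- levels(y)[1]

    p <- params
    p$seed <- seeds[2 * f]
    mdl <- fit_tsrf(tr, p)
    vm <- votes(mdl$forest, reduce_newdata(mdl, te))
    acc <- test_accuracy(vm, te$labels)
    auc <- if (nlevels(y) == 2)
      binary_auc(vm$counts[, pos] / vm$denominator, te$labels, pos)
    else NA_real_
    diag_ts <- forest_diagnostics(mdl$forest)
    rows[[length(rows) + 1]] <-
      data.frame(fold = f, model = "ts-RF", accuracy = acc, auc = auc,
                 strength = diag_ts$strength,
                 correlation = diag_ts$correlation, cs2 = diag_ts$cs2)

    if (baseline) {
      fb <- fit_forest(tr, K = params$K,
                       sampler = uniform_sampler(seq_len(m),
                                                 min(baseline_mtry, m)),
                       n_min = params$n_min, seed = seeds[2 * f + 1])
      vmb <- votes(fb, te$values)
      accb <- test_accuracy(vmb, te$labels)
      aucb <- if (nlevels(y) == 2)
        binary_auc(vmb$counts[, pos] / vmb$denominator, te$labels, pos)
      else NA_real_
      diag_b <- forest_diagnostics(fb)
      rows[[length(rows) + 1]] <-
        data.frame(fold = f, model = "RF", accuracy = accb, auc = aucb,
                   strength = diag_b$strength,
                   correlation = diag_b$correlation, cs2 = diag_b$cs2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- fold
  out
}
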