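#' Gini impurity of a node
#'
#' For class counts \eqn{n_1, \dots, n_c} with total \eqn{n}, the impurity is
#' \deqn{Gini(t) = 1 - \sum_j (n_j / n)^2,}
#' zero for a pure node and at most \eqn{1 - 1/c}.
#'
#' @param class_counts nonnegative integer counts, total >= 1.
#' @return impurity in `[0, 1)`.
#' @examples
#' gini_impurity(c(10, 0))  # 0
#' gini_impurity(c(5, 5))   # 0.5
#' @export
gini_impurity <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  n <- sum(class_counts)
  if (n < 1) stop("empty node: total count must be >= 1")
  1 - sum((class_counts / n)^2)
}

#' Weighted Gini impurity of a binary split
#'
#' \deqn{Gini_{split}(t) = \frac{N_1}{N} Gini(t_1) + \frac{N_2}{N} Gini(t_2)}
#' with \eqn{N = N_1 + N_2}. The candidate split minimizing this quantity is
#' the one a CART node takes.
#'
#' @param left_counts,right_counts per-class counts of the two children; both
#'   children must be nonempty.
#' @return weighted child impurity in `[0, 1)`.
#' @examples
#' gini_split(c(4, 0), c(1, 3))  # 0.1875
#' @export
gini_split <- function(left_counts, right_counts) {
  n1 <- sum(left_counts); n2 <- sum(right_counts)
  if (n1 < 1 || n2 < 1) stop("both children of a split must be nonempty")
  n <- n1 + n2
  (n1 / n) * gini_impurity(left_counts) + (n2 / n) * gini_impurity(right_counts)
}

#' Best CART split of a node over a candidate feature set
#'
#' Scans every candidate feature and every threshold at the midpoint between
#' consecutive distinct sorted values, returning the (feature, threshold)
#' pair minimizing the weighted child Gini impurity. Ties are broken by lower
#' impurity, then lower feature index, then lower threshold. Samples with
#' value exactly at the threshold are routed left.
#'
#' @param x numeric matrix of node samples (rows) by all features (columns).
#' @param y class labels of the node samples (factor or coercible).
#' @param candidates integer indices (1-based columns of `x`) to consider;
#'   must be nonempty.
#' @return `NULL` when every candidate is constant within the node (no valid
#'   split); otherwise a list with `feature` (1-based index), `threshold`,
#'   and `gini` (the split's weighted child impurity).
#' @export
best_split <- function(x, y, candidates) {
  if (length(candidates) == 0) stop("candidate feature set is empty")
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- factor(y)
  if (nrow(x) < 2) stop("node must contain at least 2 samples")
  res <- cpp_best_split(x, as.integer(y) - 1L, nlevels(y),
                        seq_len(nrow(x)) - 1L, as.integer(candidates) - 1L)
  if (!res$ok) return(NULL)
  list(feature = res$feature + 1L, threshold = res$threshold, gini = res$gini)
}

#' Subspace samplers for tree growth
#'
#' A sampler describes how the candidate feature set for each tree node is
#' drawn. `uniform_sampler` draws `mtry` features without replacement from a
#' single pool (plain random forest and the screening forests).
#' `stratified_sampler` draws `mtry_s` from the strongly informative pool and
#' `mtry_w` from the weakly informative pool and merges them, so every node
#' sees strongly associated features whenever that pool is nonempty (the
#' two-stage forest).
#'
#' @param pool,strong,weak integer feature indices (1-based).
#' @param mtry,mtry_s,mtry_w number of features drawn from each pool, each at
#'   most its pool size.
#' @return an object of class `subspace_sampler` consumed by [grow_tree()]
#'   and [fit_forest()].
#' @export
uniform_sampler <- function(pool, mtry) {
  stopifnot(length(pool) >= 1, mtry >= 1, mtry <= length(pool))
  structure(list(strong = as.integer(pool), weak = integer(0),
                 mtry_s = as.integer(mtry), mtry_w = 0L),
            class = "subspace_sampler")
}

#' @rdname uniform_sampler
#' @export
stratified_sampler <- function(strong, weak, mtry_s, mtry_w) {
  stopifnot(mtry_s >= 0, mtry_w >= 0, mtry_s + mtry_w >= 1,
            mtry_s <= length(strong), mtry_w <= length(weak))
  structure(list(strong = as.integer(strong), weak = as.integer(weak),
                 mtry_s = as.integer(mtry_s), mtry_w = as.integer(mtry_w)),
            class = "subspace_sampler")
}

#' Draw one candidate subspace from a sampler
#'
#' Uses R's RNG. The compiled tree engine performs the same stratified draw
#' internally with its own deterministic stream; this function exposes the
#' draw itself for inspection and testing.
#'
#' @param sampler a `subspace_sampler`.
#' @return integer vector of candidate feature indices, of length
#'   `mtry_s + mtry_w`.
#' @export
draw_subspace <- function(sampler) {
  stopifnot(inherits(sampler, "subspace_sampler"))
  c(sampler$strong[sample.int(length(sampler$strong))[seq_len(sampler$mtry_s)]],
    sampler$weak[sample.int(length(sampler$weak))[seq_len(sampler$mtry_w)]])
}

#' Grow a single unpruned CART classification tree
#'
#' Recursively splits the data, calling the sampler once per internal node
#' for candidate features and taking the [best_split()]. A node becomes a
#' leaf when it is pure, contains at most `n_min` samples, or no candidate
#' admits a valid split. No pruning is performed. At each split the Gini
#' decrease \eqn{(N(t)/N_{root}) (Gini(t) - Gini_{split}(t))} is recorded
#' against the chosen feature for importance accumulation.
#'
#' @param x numeric matrix (samples by features).
#' @param y class labels.
#' @param sampler a [uniform_sampler()] or [stratified_sampler()].
#' @param n_min minimum node size below which splitting stops (>= 1).
#' @param seed integer seed for the node-level subspace draws.
#' @return an object of class `tsrf_tree` with the recorded node table and
#'   the canonical label order.
#' @export
grow_tree <- function(x, y, sampler, n_min = 1, seed = 1) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- factor(y)
  stopifnot(nrow(x) >= 1, n_min >= 1, inherits(sampler, "subspace_sampler"))
  fit <- cpp_fit_forest(x, as.integer(y) - 1L, nlevels(y), 1L,
                        sampler$strong - 1L, sampler$weak - 1L,
                        sampler$mtry_s, sampler$mtry_w, as.integer(n_min),
                        as.double(seed), FALSE)
  structure(list(nodes = fit$trees[[1]], label_order = levels(y),
                 n_features = ncol(x),
                 importance = as.numeric(fit$importance[1, ])),
            class = "tsrf_tree")
}

#' Predict classes with a single tree
#'
#' Routes each sample from the root to a leaf by threshold comparisons
#' (values equal to a threshold go left) and returns the leaf's majority
#' class.
#'
#' @param tree a `tsrf_tree`.
#' @param x numeric matrix with the same number of feature columns the tree
#'   was grown on.
#' @return factor of predicted labels in the tree's canonical label order.
#' @export
predict_tree <- function(tree, x) {
  stopifnot(inherits(tree, "tsrf_tree"))
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (ncol(x) != tree$n_features)
    stop("expected ", tree$n_features, " feature columns, got ", ncol(x))
  p <- cpp_predict_trees(list(tree$nodes), x)[, 1]
  factor(tree$label_order[p + 1], levels = tree$label_order)
}
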