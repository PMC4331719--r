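#' Fit a bagged forest of CART trees
#'
#' Grows `K` trees, each on a bootstrap sample of size N drawn with
#' replacement. Tree k's bootstrap draw and all its node-level subspace
#' draws come from a dedicated RNG stream keyed by `(seed, k)`, so the fitted
#' forest is identical regardless of the order (or parallelism) in which
#' trees are built, and growing a longer forest leaves earlier trees
#' unchanged. With a [uniform_sampler()] over all features this is the plain
#' random-forest baseline; with a [stratified_sampler()] it is the two-stage
#' forest's engine.
#'
#' @param train a [labeled_dataset()].
#' @param K number of trees (>= 1).
#' @param sampler a `subspace_sampler` describing the per-node candidate
#'   draw.
#' @param n_min minimum node size stopping rule (default 1: grow to purity).
#' @param seed integer seed.
#' @return an object of class `tsrf_forest`: trees, per-tree bootstrap
#'   membership (1-based training indices, multiset of size N), per-tree
#'   out-of-bag index sets, per-tree Gini importance matrix (K by M), the
#'   canonical `label_order`, the stored training data and the seed.
#' @examples
#' tr <- generate_case_control(synthetic_spec(25, 25, 40, 4, seed = 2))
#' f <- fit_forest(tr$dataset, K = 25,
#'                 sampler = uniform_sampler(1:40, mtry = 6), seed = 9)
#' head(predict(f, tr$dataset$values))
#' @export
fit_forest <- function(train, K, sampler, n_min = 1, seed = 1) {
  validate_dataset(train)
  stopifnot(K >= 1, n_min >= 1, inherits(sampler, "subspace_sampler"))
  x <- train$values
  y <- train$labels
  fit <- cpp_fit_forest(x, as.integer(y) - 1L, nlevels(y), as.integer(K),
                        sampler$strong - 1L, sampler$weak - 1L,
                        sampler$mtry_s, sampler$mtry_w, as.integer(n_min),
                        as.double(seed), TRUE)
  n <- nrow(x)
  oob <- lapply(fit$bootstrap, function(b) setdiff(seq_len(n), b))
  structure(list(trees = fit$trees, bootstrap = fit$bootstrap, oob = oob,
                 importance = fit$importance, label_order = levels(y),
                 n_features = ncol(x), feature_ids = train$feature_ids,
                 train_values = x, train_labels = y,
                 sampler = sampler, n_min = as.integer(n_min),
                 seed = as.integer(seed)),
            class = "tsrf_forest")
}

#' @export
print.tsrf_forest <- function(x, ...) {
  cat("tsrf_forest: ", length(x$trees), " trees, ", x$n_features,
      " features, classes: ", paste(x$label_order, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Per-tree predictions as an N x K matrix of 1-based class indices.
tree_predictions <- function(forest, x) {
  cpp_predict_trees(forest$trees, x) + 1L
}

#' Per-class vote counts of a forest
#'
#' Counts, for each sample, how many trees vote for each class:
#' \eqn{Q(x_i, j) = \sum_k I(\hat h_k(x_i) = j)}. With `oob_only = TRUE` the
#' rows of `x` must be the forest's training samples and only trees for which
#' a sample is out-of-bag contribute, giving the out-of-bag vote matrix used
#' for strength/correlation diagnostics; samples that are in-bag for every
#' tree get denominator 0 and are flagged undefined.
#'
#' @param forest a `tsrf_forest`.
#' @param x numeric matrix of samples (defaults to the training data).
#' @param oob_only restrict each sample's votes to its out-of-bag trees.
#' @return an object of class `vote_matrix`: integer `counts` (N by classes,
#'   columns in canonical label order), integer `denominator` (voting trees
#'   per sample; row sums of `counts` equal it) and `label_order`.
#' @export
votes <- function(forest, x = NULL, oob_only = FALSE) {
  stopifnot(inherits(forest, "tsrf_forest"))
  if (is.null(x)) {
    x <- forest$train_values
  } else {
    x <- as.matrix(x); storage.mode(x) <- "double"
    if (oob_only && !isTRUE(all.equal(dim(x), dim(forest$train_values))))
      stop("oob_only votes require the training samples themselves")
  }
  if (ncol(x) != forest$n_features)
    stop("expected ", forest$n_features, " feature columns, got ", ncol(x))
  preds <- tree_predictions(forest, x)
  nclass <- length(forest$label_order)
  n <- nrow(x); K <- ncol(preds)
  if (oob_only) {
    mask <- matrix(FALSE, n, K)
    for (k in seq_len(K)) mask[forest$oob[[k]], k] <- TRUE
  } else {
    mask <- matrix(TRUE, n, K)
  }
  counts <- vapply(seq_len(nclass), function(j)
    rowSums((preds == j) & mask), numeric(n))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(NULL, forest$label_order))
  structure(list(counts = counts, denominator = as.integer(rowSums(counts)),
                 label_order = forest$label_order),
            class = "vote_matrix")
}

# Majority class per row of a vote_matrix; ties go to the earliest class in
# canonical label order. Rows with denominator 0 give NA.
vote_argmax <- function(vm) {
  idx <- apply(vm$counts, 1, which.max)  # which.max takes the first maximum
  out <- factor(vm$label_order[idx], levels = vm$label_order)
  out[vm$denominator == 0] <- NA
  out
}

#' Predict classes with a forest
#'
#' Aggregates the per-tree votes and returns, for each sample, the class with
#' the most votes; ties are resolved in favor of the earliest class in
#' canonical label order.
#'
#' @param object a `tsrf_forest`.
#' @param x numeric matrix of samples (defaults to the training data).
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.tsrf_forest <- function(object, x = NULL, ...) {
  vote_argmax(votes(object, x))
}

#' Raw Gini importance of a forest
#'
#' The importance of feature f is the mean, over the K trees, of the summed
#' recorded Gini decreases \eqn{(N(t)/N_{root})(Gini(t) - Gini_{split}(t))}
#' attributed to f in that tree. Features never chosen for a split score 0;
#' all scores are nonnegative. Averaging over trees (rather than summing)
#' makes scores comparable across forests of different sizes; ranking is
#' unaffected.
#'
#' @param forest a `tsrf_forest`.
#' @return named numeric vector of length M.
#' @export
raw_importance <- function(forest) {
  stopifnot(inherits(forest, "tsrf_forest"))
  stats::setNames(colMeans(forest$importance), forest$feature_ids)
}

#' Save or load a fitted model
#'
#' Serializes a fitted forest or two-stage model to a single RDS file
#' containing every field of the object (trees, thresholds, bootstrap and
#' out-of-bag membership, label order, screen result, parameters, seed), so
#' a reloaded model reproduces predictions exactly.
#'
#' @param object a `tsrf_forest` or `tsrf_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "tsrf_forest") || inherits(object, "tsrf_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!(inherits(obj, "tsrf_forest") || inherits(obj, "tsrf_model")))
    stop("file does not contain a saved tsrf model: ", path)
  obj
}
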