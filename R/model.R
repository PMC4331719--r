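#' Hyperparameters of the two-stage random forest
#'
#' @param R screening replicates (default 30).
#' @param theta stage-1 Wilcoxon significance threshold (default 0.05).
#' @param alpha stage-2 chi-squared threshold (default 0.05).
#' @param K trees in the final forest (default 500).
#' @param mtry per-node subspace size of the final forest; `NULL` (default)
#'   means `floor(sqrt(|informative set|))`, floored at 2 when both feature
#'   groups are nonempty.
#' @param n_min minimum node size (default 1).
#' @param K_screen trees per screening forest (default 50).
#' @param mtry_screen subspace size of the screening forests; `NULL` means
#'   `floor(0.1 * M)`.
#' @param seed integer seed governing every random draw of the fit.
#' @return an object of class `tsrf_params`.
#' @export
tsrf_params <- function(R = 30, theta = 0.05, alpha = 0.05, K = 500,
                        mtry = NULL, n_min = 1, K_screen = 50,
                        mtry_screen = NULL, seed = 1) {
  stopifnot(R >= 2, theta > 0, theta < 1, alpha > 0, alpha < 1, K >= 1,
            n_min >= 1, K_screen >= 1)
  if (!is.null(mtry)) stopifnot(mtry >= 1)
  structure(list(R = as.integer(R), theta = theta, alpha = alpha,
                 K = as.integer(K), mtry = mtry, n_min = as.integer(n_min),
                 K_screen = as.integer(K_screen), mtry_screen = mtry_screen,
                 seed = as.integer(seed)),
            class = "tsrf_params")
}

#' Fit a two-stage quality-based random forest
#'
#' End-to-end procedure: (1-2) extend the data with permuted shadow features
#' and compute R replicates of raw Gini importance with screening forests;
#' (3-4) per-feature one-sided Wilcoxon test against the shadow maxima,
#' removing features with p-value above `theta`; (5) chi-squared partition of
#' the survivors into strongly and weakly informative groups; (6-7) grow a
#' bagged forest of `K` CART trees whose per-node candidate subspaces are
#' drawn proportionally from both groups (always including a strong feature
#' when the strong group is nonempty); (8) predict by majority vote. The fit
#' is fully determined by the data and parameters, including the seed.
#'
#' The final forest stores the reduced feature matrix (informative columns
#' only); prediction looks features up by ID, so new data must carry the
#' training feature set.
#'
#' @param train a [labeled_dataset()] with >= 2 classes.
#' @param params a [tsrf_params()].
#' @return an object of class `tsrf_model`: `screen` (a `screen_result`),
#'   `forest` (a [fit_forest()] result over the informative columns),
#'   `params`, `label_order`, `feature_ids` (the full training feature set)
#'   and the realized `mtry_s`/`mtry_w`.
#' @examples
#' tr <- generate_case_control(synthetic_spec(30, 30, 60, 5,
#'                                            effect_delta = 0.35, seed = 3))
#' m <- fit_tsrf(tr$dataset, tsrf_params(R = 5, K = 50, K_screen = 20,
#'                                       seed = 11))
#' table(predict(m, tr$dataset), tr$dataset$labels)
#' @export
fit_tsrf <- function(train, params = tsrf_params()) {
  validate_dataset(train)
  stopifnot(inherits(params, "tsrf_params"))
  seeds <- derive_seeds(params$seed, 2)
  scr <- screen_features(train, R = params$R, K_screen = params$K_screen,
                         mtry_screen = params$mtry_screen,
                         theta = params$theta, alpha = params$alpha,
                         n_min = params$n_min, seed = seeds[1])
  if (length(scr$informative) == 0)
    stop("no informative features at theta = ", params$theta,
         ": every feature's importance is indistinguishable from the shadow",
         " maxima. Lower theta only with caution; more samples or a larger",
         " R may help if signal is expected.")
  reduced <- labeled_dataset(
    train$values[, scr$informative, drop = FALSE], train$labels,
    feature_ids = train$feature_ids[scr$informative],
    sample_ids = train$sample_ids, feature_kind = train$feature_kind)
  ns <- length(scr$strong); nw <- length(scr$weak)
  mtry <- params$mtry
  if (is.null(mtry)) mtry <- floor(sqrt(ns + nw))
  if (ns > 0 && nw > 0) mtry <- max(2, mtry)
  mtry <- max(1, min(mtry, ns + nw))
  sz <- subspace_sizes(mtry, ns, nw)
  # indices within the reduced matrix
  strong_r <- match(scr$strong, scr$informative)
  weak_r <- match(scr$weak, scr$informative)
  sampler <- stratified_sampler(strong_r, weak_r, sz$mtry_s, sz$mtry_w)
  forest <- fit_forest(reduced, K = params$K, sampler = sampler,
                       n_min = params$n_min, seed = seeds[2])
  structure(list(screen = scr, forest = forest, params = params,
                 label_order = forest$label_order,
                 feature_ids = train$feature_ids,
                 mtry = mtry, mtry_s = sz$mtry_s, mtry_w = sz$mtry_w),
            class = "tsrf_model")
}

#' @export
print.tsrf_model <- function(x, ...) {
  cat("tsrf_model: ", length(x$forest$trees), " trees on ",
      length(x$screen$informative), "/", length(x$feature_ids),
      " informative features (strong ", length(x$screen$strong), ", weak ",
      length(x$screen$weak), "); mtry = ", x$mtry, " (", x$mtry_s, "+",
      x$mtry_w, ")\n", sep = "")
  invisible(x)
}

# Map new data onto the model's informative columns, by feature ID when
# available, else by position against the full training feature set.
reduce_newdata <- function(model, newdata) {
  if (inherits(newdata, "labeled_dataset")) {
    x <- newdata$values
    colnames(x) <- newdata$feature_ids
  } else {
    x <- as.matrix(newdata)
  }
  want <- model$forest$feature_ids
  if (!is.null(colnames(x))) {
    miss <- setdiff(want, colnames(x))
    if (length(miss) > 0)
      stop("newdata lacks model features: ",
           paste(utils::head(miss, 5), collapse = ", "))
    x <- x[, want, drop = FALSE]
  } else {
    if (ncol(x) != length(model$feature_ids))
      stop("unnamed newdata must have the full training feature set (",
           length(model$feature_ids), " columns), got ", ncol(x))
    x <- x[, model$screen$informative, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}

#' Predict with a two-stage random forest
#'
#' Delegates to the underlying forest's majority vote over the model's
#' informative features.
#'
#' @param object a `tsrf_model`.
#' @param newdata a `labeled_dataset` or matrix carrying the training
#'   features (by column name, or all M columns positionally).
#' @param type `"class"` for labels, `"votes"` for per-class vote fractions.
#' @param ... unused.
#' @return factor of labels, or a numeric matrix of vote fractions with one
#'   column per class (rows sum to 1).
#' @export
predict.tsrf_model <- function(object, newdata, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  x <- reduce_newdata(object, newdata)
  vm <- votes(object$forest, x)
  if (type == "class") return(vote_argmax(vm))
  vm$counts / vm$denominator
}

#' Per-class vote fractions
#'
#' The fraction of trees voting for each class; the column of the designated
#' positive class is the score used for AUC.
#'
#' @param model a `tsrf_model`.
#' @param newdata as in [predict.tsrf_model()].
#' @return numeric matrix, rows summing to 1, columns in canonical label
#'   order.
#' @export
vote_scores <- function(model, newdata) {
  predict(model, newdata, type = "votes")
}

#' Ranked feature report
#'
#' Orders all screened features by mean replicate importance (descending),
#' breaking ties by Wilcoxon p-value (ascending) and then feature index, and
#' reports each feature's screening group and p-values — the layout of a
#' ranked SNP table.
#'
#' @param model a `tsrf_model`.
#' @param top_n number of rows to report (truncated to M; 0 gives an empty
#'   report).
#' @return data.frame with columns `rank`, `feature_id`, `group` (`"strong"`,
#'   `"weak"` or `"removed"`), `wilcoxon_p`, `chi2_p` (NA for removed
#'   features) and `importance`.
#' @export
rank_features <- function(model, top_n = 25) {
  stopifnot(inherits(model, "tsrf_model"), top_n >= 0)
  scr <- model$screen
  m <- length(scr$feature_ids)
  group <- rep("removed", m)
  group[scr$weak] <- "weak"
  group[scr$strong] <- "strong"
  chi2 <- rep(NA_real_, m)
  chi2[scr$informative] <- scr$chi2_p
  ord <- order(-scr$mean_importance, scr$wilcoxon_p, seq_len(m))
  top <- utils::head(ord, min(top_n, m))
  data.frame(rank = seq_along(top),
             feature_id = scr$feature_ids[top],
             group = group[top],
             wilcoxon_p = unname(scr$wilcoxon_p[top]),
             chi2_p = chi2[top],
             importance = unname(scr$mean_importance[top]),
             stringsAsFactors = FALSE)
}

#' Write or read a ranked screen report
#'
#' Plain TSV serialization of [rank_features()] output.
#'
#' @param report data.frame from [rank_features()].
#' @param path file path.
#' @return `write_screen_report` returns `path` invisibly;
#'   `read_screen_report` returns the data.frame.
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
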