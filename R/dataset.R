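#' Labeled feature matrix for case-control classification
#'
#' Container for a samples-by-features matrix of genotype dosages (counts of
#' the minor allele, coded 0/1/2) or continuous measurements (e.g. gene
#' expression), together with a class label per sample. All downstream
#' machinery of the package (screening, forests, evaluation) operates on this
#' type.
#'
#' @param values numeric matrix, samples in rows, features in columns; no
#'   missing values. For genotype data every entry must be 0, 1 or 2.
#' @param labels class label per sample (character or factor); at least two
#'   distinct classes, each present at least once. The canonical label order
#'   used for vote tie-breaking is the sorted order of the distinct labels.
#' @param feature_ids unique feature names (e.g. rs numbers); defaults to
#'   column names of `values`.
#' @param sample_ids unique sample names; defaults to row names of `values`.
#' @param feature_kind `"genotype"` (entries restricted to 0/1/2) or
#'   `"continuous"`.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `values`, `feature_ids`, `sample_ids`, `labels` (factor with canonical
#'   level order) and `feature_kind`.
#' @examples
#' x <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("rs1", "rs2")))
#' d <- labeled_dataset(x, c("case", "case", "control"))
#' d
#' @export
labeled_dataset <- function(values, labels, feature_ids = colnames(values),
                            sample_ids = rownames(values),
                            feature_kind = c("genotype", "continuous")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  labels <- factor(as.character(labels))
  d <- structure(list(values = unname(values),
                      feature_ids = as.character(feature_ids),
                      sample_ids = as.character(sample_ids),
                      labels = labels,
                      feature_kind = feature_kind),
                 class = "labeled_dataset")
  validate_dataset(d)
  d
}

#' Validate a labeled_dataset
#'
#' Checks every invariant of the container: matching dimensions, unique IDs,
#' no missing values, genotype entries in \{0, 1, 2\}, and at least two
#' classes each observed at least once. Called by all constructors and
#' readers; exported so user-assembled objects can be checked too.
#'
#' @param d a `labeled_dataset`.
#' @return `d`, invisibly; errors describe the first violation found.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "labeled_dataset"))
  v <- d$values
  n <- nrow(v); m <- ncol(v)
  if (length(d$sample_ids) != n)
    stop("sample_ids length (", length(d$sample_ids),
         ") does not match number of rows (", n, ")")
  if (length(d$feature_ids) != m)
    stop("feature_ids length (", length(d$feature_ids),
         ") does not match number of columns (", m, ")")
  if (anyDuplicated(d$sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(d$sample_ids[duplicated(d$sample_ids)]), collapse = ", "))
  if (anyDuplicated(d$feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(d$feature_ids[duplicated(d$feature_ids)]), collapse = ", "))
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", d$sample_ids[bad[1]], "', feature '",
         d$feature_ids[bad[2]], "'; missing data are not supported")
  }
  if (d$feature_kind == "genotype" && !all(v %in% c(0, 1, 2))) {
    bad <- which(!(v %in% c(0, 1, 2)))[1]
    i <- (bad - 1) %% n + 1; j <- (bad - 1) %/% n + 1
    stop("genotype value ", v[bad], " outside {0,1,2} at sample '",
         d$sample_ids[i], "', feature '", d$feature_ids[j], "'")
  }
  if (length(d$labels) != n)
    stop("labels length (", length(d$labels),
         ") does not match number of samples (", n, ")")
  if (nlevels(d$labels) < 2)
    stop("need at least 2 classes, got ", nlevels(d$labels))
  if (any(tabulate(d$labels, nbins = nlevels(d$labels)) == 0))
    stop("every class must appear at least once")
  invisible(d)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset: ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", x$feature_kind, ")\n", sep = "")
  cat("classes:",
      paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$values)

#' Read a labeled dataset from disk
#'
#' Two dialects are supported. `"tsv"`: a UTF-8 tab-delimited file with a
#' header row; the first column holds sample IDs, one named column holds the
#' class labels, and every remaining column is a feature. `"plink_raw"`: the
#' space-delimited PLINK `.raw` additive-dosage export with header
#' `FID IID PAT MAT SEX PHENOTYPE SNP1 ...`; the dosage columns are the
#' features and PHENOTYPE supplies the labels (1 mapped to `"control"`, 2 to
#' `"case"`; any other value is an error).
#'
#' @param path file to read.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param label_column name of the label column (tsv only).
#' @param feature_kind `"genotype"` or `"continuous"`; genotype entries are
#'   validated against \{0, 1, 2\}.
#' @return a [labeled_dataset()] with feature order as in the file.
#' @export
read_dataset <- function(path, format = c("tsv", "plink_raw"),
                         label_column = "label",
                         feature_kind = c("genotype", "continuous")) {
  format <- match.arg(format)
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("file has no data rows: ", path)
  sep <- if (format == "tsv") "\t" else " "
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  nf <- length(header)
  widths <- lengths(fields)
  if (any(widths != nf)) {
    bad <- which(widths != nf)[1]
    stop("ragged row at line ", bad, ": expected ", nf, " fields, found ",
         widths[bad])
  }
  body <- do.call(rbind, fields[-1])
  if (format == "tsv") {
    li <- match(label_column, header)
    if (is.na(li)) stop("label column '", label_column, "' not found in header")
    if (li == 1) stop("label column cannot be the sample-ID (first) column")
    sample_ids <- body[, 1]
    labels <- body[, li]
    fcols <- setdiff(seq_len(nf), c(1L, li))
  } else {
    req <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (nf < 7 || !identical(header[1:6], req))
      stop("not a PLINK .raw header: expected columns ",
           paste(req, collapse = " "))
    sample_ids <- body[, 2]
    phen <- body[, 6]
    if (!all(phen %in% c("1", "2")))
      stop("PHENOTYPE values must be 1 (control) or 2 (case); found: ",
           paste(unique(setdiff(phen, c("1", "2"))), collapse = ", "))
    labels <- ifelse(phen == "2", "case", "control")
    fcols <- 7:nf
  }
  if (length(fcols) == 0) stop("no feature columns in ", path)
  vals <- suppressWarnings(matrix(as.numeric(body[, fcols, drop = FALSE]),
                                  nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing feature value at sample '",
         sample_ids[bad[1]], "', feature '", header[fcols][bad[2]], "'")
  }
  labeled_dataset(vals, labels, feature_ids = header[fcols],
                  sample_ids = sample_ids, feature_kind = feature_kind)
}

#' Write a labeled dataset to a TSV file
#'
#' Emits the tab-delimited dialect read back by [read_dataset()]: sample IDs
#' in the first column, labels in a named column, features after it.
#' Round-trips exactly for genotype data; continuous values are written with
#' full (17 significant digit) precision.
#'
#' @param d a valid `labeled_dataset` with at least one feature.
#' @param path output file.
#' @param label_column header name for the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, label_column = "label") {
  validate_dataset(d)
  if (ncol(d$values) == 0)
    stop("refusing to write a dataset with no features")
  if (label_column %in% d$feature_ids)
    stop("label column name '", label_column, "' collides with a feature ID")
  fmt <- function(x) {
    if (d$feature_kind == "genotype") format(x, scientific = FALSE)
    else format(x, digits = 17, scientific = FALSE)
  }
  header <- paste(c("sample_id", label_column, d$feature_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(d$values)), function(i) {
    paste(c(d$sample_ids[i], as.character(d$labels[i]),
            vapply(d$values[i, ], fmt, "")), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
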