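#' Specification of a synthetic case-control genotype study
#'
#' Describes a balanced-design case-control cohort in which most SNPs are
#' null and a small planted set is associated with disease through a shift in
#' minor-allele frequency. Genotypes follow a per-class Hardy-Weinberg
#' (binomial dosage) model: every SNP in controls, and null SNPs in cases,
#' draw dosage as Binomial(2, `control_maf`); planted SNPs in cases draw as
#' Binomial(2, `control_maf + effect_delta`).
#'
#' @param n_cases,n_controls samples per class.
#' @param m_features total number of SNPs.
#' @param m_informative number of planted (associated) SNPs, at most
#'   `m_features`.
#' @param control_maf minor-allele frequency in controls, in (0, 0.5].
#' @param effect_delta additive allele-frequency shift in cases for planted
#'   SNPs, >= 0; `control_maf + effect_delta` must not exceed 1.
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_case_control()]
#' @export
synthetic_spec <- function(n_cases, n_controls, m_features, m_informative,
                           control_maf = 0.2, effect_delta = 0.3, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, m_features >= 1,
            m_informative >= 0, m_informative <= m_features,
            control_maf > 0, control_maf <= 0.5, effect_delta >= 0,
            control_maf + effect_delta <= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 m_features = as.integer(m_features),
                 m_informative = as.integer(m_informative),
                 control_maf = control_maf, effect_delta = effect_delta,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a case-control genotype dataset with planted associated SNPs
#'
#' Draws genotype dosages under the binomial model of [synthetic_spec()].
#' The planted SNPs are the first `m_informative` columns (their IDs carry a
#' `snpI` prefix; null SNPs are `snpN`), so the ground truth is recoverable
#' both from `informative_ids` and by eye.
#'
#' @param spec a `synthetic_spec`.
#' @return an object of class `synthetic_truth`: list with `dataset` (a
#'   [labeled_dataset()] with labels `"case"`/`"control"`) and
#'   `informative_ids` (character vector of the planted feature IDs).
#' @examples
#' tr <- generate_case_control(synthetic_spec(20, 20, 50, 5, seed = 7))
#' tr$dataset
#' tr$informative_ids
#' @export
generate_case_control <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_cases + spec$n_controls
  m <- spec$m_features
  mi <- spec$m_informative
  ids <- c(if (mi > 0) sprintf("snpI%03d", seq_len(mi)),
           if (m > mi) sprintf("snpN%05d", seq_len(m - mi)))
  labels <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  p <- matrix(spec$control_maf, nrow = n, ncol = m)
  if (mi > 0)
    p[seq_len(spec$n_cases), seq_len(mi)] <- spec$control_maf + spec$effect_delta
  vals <- with_seed(spec$seed, {
    matrix(stats::rbinom(n * m, size = 2, prob = p), nrow = n, ncol = m)
  })
  d <- labeled_dataset(vals, labels, feature_ids = ids,
                       sample_ids = sprintf("s%05d", seq_len(n)),
                       feature_kind = "genotype")
  structure(list(dataset = d, informative_ids = ids[seq_len(mi)]),
            class = "synthetic_truth")
}

#' Generate a continuous-feature (expression-like) dataset with class shift
#'
#' Gaussian analogue of [generate_case_control()] for emulating
#' gene-expression classification: every feature is standard normal noise
#' except the planted ones, whose case-class mean is shifted by
#' `effect_delta` standard deviations.
#'
#' @param spec a `synthetic_spec`; `control_maf` is ignored and
#'   `effect_delta` is reinterpreted as the standardized mean shift.
#' @return a `synthetic_truth` whose dataset has `feature_kind = "continuous"`
#'   and feature IDs prefixed `gI`/`gN`.
#' @export
generate_continuous <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_cases + spec$n_controls
  m <- spec$m_features
  mi <- spec$m_informative
  ids <- c(if (mi > 0) sprintf("gI%03d", seq_len(mi)),
           if (m > mi) sprintf("gN%05d", seq_len(m - mi)))
  labels <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  mu <- matrix(0, nrow = n, ncol = m)
  if (mi > 0) mu[seq_len(spec$n_cases), seq_len(mi)] <- spec$effect_delta
  vals <- with_seed(spec$seed, {
    matrix(stats::rnorm(n * m, mean = mu), nrow = n, ncol = m)
  })
  d <- labeled_dataset(vals, labels, feature_ids = ids,
                       sample_ids = sprintf("s%05d", seq_len(n)),
                       feature_kind = "continuous")
  structure(list(dataset = d, informative_ids = ids[seq_len(mi)]),
            class = "synthetic_truth")
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
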