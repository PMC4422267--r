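#' qRT-PCR-style double normalization
#'
#' Relative expression computed the way stem-loop qRT-PCR series are reported
#' here: each sample's target quantity is first normalized by a reference RNA
#' (e.g. 5.8S rRNA) measured in the same sample, then the whole series is
#' scaled so the designated baseline sample (superior spikelets at 10 DAF)
#' equals exactly 1.0:
#' \deqn{v_s = (T_s / R_s) / (T_{base} / R_{base})}
#' The result is invariant to any global rescaling of targets or references.
#'
#' @param raw_target named numeric vector of target quantities per sample.
#' @param raw_reference named numeric vector of reference-RNA quantities per
#'   sample (same names), strictly positive.
#' @param baseline_sample name of the baseline sample.
#' @return named numeric vector of relative expressions; baseline exactly 1.
#' @export
double_normalize <- function(raw_target, raw_reference, baseline_sample) {
  if (is.null(names(raw_target)) || is.null(names(raw_reference))) {
    abort("target and reference vectors must be named by sample")
  }
  if (!setequal(names(raw_target), names(raw_reference))) {
    abort("target and reference sample names differ")
  }
  raw_reference <- raw_reference[names(raw_target)]
  if (any(raw_reference <= 0)) abort("reference quantities must be positive")
  if (!baseline_sample %in% names(raw_target)) {
    abort("baseline sample '", baseline_sample, "' not present")
  }
  ratio <- raw_target / raw_reference
  ratio / ratio[[baseline_sample]]
}

#' Log2 expression matrix for profile work
#'
#' Elementwise binary logarithm of a floored TPM matrix — the scale on which
#' heat maps and profile clustering operate. Zeros are a contract violation
#' (the floor must have been applied) and raise an error rather than
#' producing -Inf.
#'
#' @param expr floored TPM matrix, all entries > 0.
#' @return matrix of log2 values, same shape.
#' @export
log2_profile_matrix <- function(expr) {
  if (any(expr <= 0)) {
    abort("expression matrix contains non-positive cells; apply_floor() first")
  }
  log2(expr)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of entity profiles with average linkage on the
#' correlation distance \eqn{1 - r} (Pearson, across libraries) — standard
#' expression heat-map practice. Deterministic given its inputs; reordering
#' the input rows permutes the assignments but never changes the partition.
#' Zero-variance profiles have no defined correlation and are rejected.
#'
#' @param log2_matrix entities x libraries matrix (log2 scale).
#' @param k number of flat clusters to cut; default 2.
#' @param method linkage passed to [stats::hclust()].
#' @return list with \code{clusters} (named integer vector), \code{order}
#'   (dendrogram leaf order, entity names) and \code{hclust} (the tree).
#' @export
cluster_profiles <- function(log2_matrix, k = 2L, method = "average") {
  if (nrow(log2_matrix) < 2L) abort("need at least 2 entities to cluster")
  if (k > nrow(log2_matrix)) abort("k exceeds the number of entities")
  sds <- apply(log2_matrix, 1L, sd)
  if (any(sds == 0)) {
    abort("zero-variance profile(s): ",
          paste(utils::head(rownames(log2_matrix)[sds == 0], 3L), collapse = ", "))
  }
  d <- as.dist(1 - cor(t(log2_matrix)))
  hc <- hclust(d, method = method)
  cl <- cutree(hc, k = k)
  list(clusters = cl, order = rownames(log2_matrix)[hc$order], hclust = hc)
}

#' Correlation between a miRNA and its putative target
#'
#' Pearson or Spearman correlation of a miRNA expression series with a target
#' series across stages; post-transcriptional repression predicts a negative
#' coefficient. Constant series have no defined correlation and are reported
#' as \code{NA} with a reason, never as 0.
#'
#' @param mirna_series,target_series numeric vectors, equal length >= 3.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return data.frame (one row): \code{method}, \code{correlation},
#'   \code{n}, \code{reason} (\code{NA} unless undefined).
#' @export
mirna_target_correlation <- function(mirna_series, target_series,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(mirna_series)
  if (n < 3L || length(target_series) != n) {
    abort("series must have equal length >= 3")
  }
  if (sd(mirna_series) == 0 || sd(target_series) == 0) {
    return(data.frame(method = method, correlation = NA_real_, n = n,
                      reason = "constant series: correlation undefined",
                      stringsAsFactors = FALSE))
  }
  data.frame(method = method,
             correlation = cor(mirna_series, target_series, method = method),
             n = n, reason = NA_character_, stringsAsFactors = FALSE)
}
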