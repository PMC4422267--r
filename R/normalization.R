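#' Normalize raw counts to transcripts per million (TPM)
#'
#' Each cell becomes \code{count * 1e6 / total_clean_reads} of its library.
#' The denominator is the library's total clean reads — the same \eqn{N} used
#' by the exact two-library test — not the sum of miRNA-mapped reads, so
#' normalization and testing share one scale. No zero-floor is applied here;
#' see [apply_floor()].
#'
#' @param counts integer matrix of raw counts (entities x libraries).
#' @param meta library metadata as from [read_metadata()]; every column of
#'   \code{counts} must have a record.
#' @return numeric matrix of TPM values, same shape and dimnames.
#' @export
tpm_normalize <- function(counts, meta) {
  meta <- validate_metadata(meta)
  libs <- colnames(counts)
  hit <- match(libs, meta$library_id)
  if (anyNA(hit)) {
    abort("no metadata for library: ", libs[is.na(hit)][1L])
  }
  totals <- meta$total_clean_reads[hit]
  sweep(counts + 0, 2L, totals, function(x, n) x * 1e6 / n)
}

#' Floor zero expression values
#'
#' Replaces cells that are exactly zero — miRNAs not detected in a library —
#' with a small positive floor (default 0.01 TPM) so that expression ratios
#' and their binary logarithms are always defined. Nonzero values below the
#' floor are left untouched; the operation is idempotent.
#'
#' @param expr numeric TPM matrix.
#' @param floor positive replacement value for exact zeros.
#' @return matrix with zeros replaced by \code{floor}.
#' @export
apply_floor <- function(expr, floor = 0.01) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0) {
    abort("floor must be a single positive number")
  }
  expr[expr == 0] <- floor
  expr
}

#' Filter entities by minimum abundance
#'
#' An entity is retained only if its expression is strictly higher than
#' \code{threshold} TPM in at least one library; entities below the threshold
#' everywhere are set aside (their differential expression is ignored). The
#' returned partition is exhaustive and disjoint, and is unaffected by whether
#' [apply_floor()] has run, provided \code{floor < threshold} (enforced).
#'
#' @param expr numeric TPM matrix (floored or not).
#' @param threshold strict lower bound on the per-entity maximum TPM.
#' @param floor the zero-floor in force, used only for the sanity check.
#' @return list with elements \code{kept} (sub-matrix) and \code{dropped_ids}
#'   (character vector).
#' @export
abundance_filter <- function(expr, threshold = 10, floor = 0.01) {
  if (threshold <= floor) {
    abort("abundance threshold (", threshold, ") must exceed the zero floor (",
          floor, ")", class = "spikefill_config_error")
  }
  keep <- apply(expr, 1L, max) > threshold
  list(kept = expr[keep, , drop = FALSE],
       dropped_ids = rownames(expr)[!keep])
}

#' Per-library and pooled read-length distributions
#'
#' Converts per-library read-length histograms into fractions of total reads,
#' mirroring the length-distribution summaries used to contrast the dominant
#' 24-nt and secondary 21-nt small-RNA populations.
#'
#' @param histograms integer matrix of read counts, lengths in rows (rownames
#'   are lengths in nt, within 18--30), libraries in columns.
#' @return list with \code{per_library} (matrix of fractions, same shape) and
#'   \code{pooled} (named vector of fractions across all libraries).
#' @export
length_distribution <- function(histograms) {
  stopifnot(is.matrix(histograms))
  lens <- as.integer(rownames(histograms))
  if (anyNA(lens) || any(lens < 18L) || any(lens > 30L)) {
    abort("histogram rownames must be read lengths within 18-30 nt")
  }
  totals <- colSums(histograms)
  if (any(totals == 0)) {
    abort("empty histogram for library: ",
          colnames(histograms)[totals == 0][1L])
  }
  per_lib <- sweep(histograms, 2L, totals, "/")
  pooled <- rowSums(histograms) / sum(histograms)
  list(per_library = per_lib, pooled = pooled)
}

#' Classify reads into annotation classes by exact match
#'
#' Assigns each read to the first class (in priority order) whose sequence set
#' contains it exactly and full-length, else to \code{unannotated}. This is a
#' deliberate, auditable replacement for database/alignment annotation, which
#' sits upstream of this package. Counts are conserved: class counts plus
#' unannotated always sum to the number of input reads.
#'
#' @param reads character vector of read sequences (a multiset; duplicates
#'   count multiply).
#' @param class_sets named list of character vectors of class sequences, as
#'   from [read_class_sets()].
#' @param priority class names in match-priority order; classes absent from
#'   \code{class_sets} are skipped.
#' @return named integer vector of read counts per class plus
#'   \code{unannotated}.
#' @export
classify_reads <- function(reads, class_sets,
                           priority = c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA")) {
  if (length(class_sets) == 0L) {
    warning("empty class set map: all reads unannotated")
    return(setNames(length(reads), "unannotated"))
  }
  stopifnot(!is.null(names(class_sets)))
  order_used <- c(intersect(priority, names(class_sets)),
                  setdiff(names(class_sets), priority))
  reads <- toupper(reads)
  assigned <- rep(NA_character_, length(reads))
  for (cl in order_used) {
    hit <- is.na(assigned) & reads %in% toupper(class_sets[[cl]])
    assigned[hit] <- cl
  }
  assigned[is.na(assigned)] <- "unannotated"
  counts <- vapply(c(order_used, "unannotated"),
                   function(cl) sum(assigned == cl), integer(1L))
  counts
}
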