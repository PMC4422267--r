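#' Evaluate one novel-miRNA candidate
#'
#' A candidate emerging from hairpin discovery is accepted as a novel miRNA
#' when at least one of three lines of evidence holds:
#' \describe{
#'   \item{H (highly expressed)}{mature-sequence expression above
#'     \code{tpm_high} TPM (strictly more than 50 TPM by default) in at least
#'     one library;}
#'   \item{F (frequently detected)}{mature sequence detected (TPM strictly
#'     above \code{detection_floor}, default 0) in at least half of the
#'     libraries;}
#'   \item{S (star evidence)}{the passenger strand (miRNA*) observed in at
#'     least one library — direct biogenesis evidence.}
#' }
#' The detection-breadth quorum is \code{2 * detected >= n_libraries}. With
#' ten libraries that is five: the published evidence assignments require a
#' candidate seen in exactly half the libraries to pass the breadth criterion
#' while one seen in four does not, which pins the quorum to "at least half"
#' rather than a strict majority. The quorum is configurable via
#' \code{min_detected} for designs where a stricter reading is wanted.
#'
#' Each criterion depends only on its own inputs, and raising any TPM value
#' can never turn an accepted candidate into a rejected one.
#'
#' @param tpm_by_library named numeric vector: mature TPM per library.
#' @param star_detected logical vector (or single flag): miRNA* seen per
#'   library.
#' @param n_libraries number of libraries in the experiment.
#' @param tpm_high strict TPM threshold for the H criterion.
#' @param detection_floor TPM above which a mature sequence counts as
#'   detected.
#' @param min_detected detection quorum for F; default \code{ceiling(n/2)}.
#' @return list with \code{accepted} (logical) and \code{evidence_codes}
#'   (character subset of \code{c("H", "F", "S")}).
#' @export
evaluate_candidate <- function(tpm_by_library, star_detected = FALSE,
                               n_libraries = length(tpm_by_library),
                               tpm_high = 50, detection_floor = 0,
                               min_detected = ceiling(n_libraries / 2)) {
  if (length(tpm_by_library) == 0L) abort("empty TPM map for candidate")
  if (n_libraries < 1L) abort("n_libraries must be >= 1")
  if (any(tpm_by_library < 0)) abort("TPM values must be non-negative")
  codes <- character(0)
  if (max(tpm_by_library) > tpm_high) codes <- c(codes, "H")
  if (sum(tpm_by_library > detection_floor) >= min_detected) codes <- c(codes, "F")
  if (any(star_detected)) codes <- c(codes, "S")
  list(accepted = length(codes) > 0L, evidence_codes = codes)
}

#' Evaluate a table of novel-miRNA candidates
#'
#' Applies [evaluate_candidate()] to every row of a candidate TPM matrix.
#' Rejected candidates are retained in the output with empty evidence so the
#' decision trail is auditable; decisions are independent across candidates
#' and of their order.
#'
#' @param tpm matrix of mature-sequence TPM, candidates x libraries.
#' @param star logical matrix (same shape) or named logical vector of
#'   per-candidate star evidence; default none.
#' @param ... passed to [evaluate_candidate()] (\code{tpm_high},
#'   \code{detection_floor}, \code{min_detected}).
#' @return data.frame: \code{candidate_id}, \code{accepted}, \code{evidence}
#'   (codes collapsed with ","), \code{max_tpm}, \code{n_detected}.
#' @export
evaluate_all <- function(tpm, star = NULL, ...) {
  stopifnot(is.matrix(tpm))
  ids <- rownames(tpm)
  if (is.null(star)) star <- setNames(rep(FALSE, nrow(tpm)), ids)
  out <- lapply(seq_len(nrow(tpm)), function(i) {
    st <- if (is.matrix(star)) star[i, ] else star[[ids[i]]] %||% FALSE
    d <- evaluate_candidate(tpm[i, ], star_detected = st,
                            n_libraries = ncol(tpm), ...)
    data.frame(candidate_id = ids[i],
               accepted = d$accepted,
               evidence = paste(d$evidence_codes, collapse = ","),
               max_tpm = max(tpm[i, ]),
               n_detected = sum(tpm[i, ] > 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(candidate_id = character(0), accepted = logical(0),
                      evidence = character(0), max_tpm = numeric(0),
                      n_detected = integer(0))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a novel-candidate table
#'
#' Reads a TSV of candidates — columns \code{candidate_id}, \code{sequence},
#' \code{length}, then one TPM column per library — plus an optional
#' star-evidence TSV (\code{candidate_id} column followed by one logical/0-1
#' column per library). The package ships such a fixture: the published table
#' of thirteen novel rice miRNAs (`table1_novel_mirnas.tsv`) with a synthetic
#' star-flag companion (`table1_star_synthetic.tsv`; the source table reports
#' only that a star read existed somewhere, not in which library).
#'
#' @param path candidate TSV.
#' @param star_path optional star-evidence TSV.
#' @return list with \code{info} (data.frame id/sequence/length), \code{tpm}
#'   (matrix) and \code{star} (logical matrix or NULL).
#' @export
read_novel_candidates <- function(path, star_path = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("candidate_id", "sequence", "length")
  if (!all(need %in% colnames(df))) {
    abort("candidate table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$length != nchar(df$sequence))) {
    abort("length column disagrees with sequence length for: ",
          df$candidate_id[df$length != nchar(df$sequence)][1L])
  }
  lib_cols <- setdiff(colnames(df), need)
  tpm <- as.matrix(df[, lib_cols, drop = FALSE])
  storage.mode(tpm) <- "double"
  if (any(is.na(tpm)) || any(tpm < 0)) abort("TPM cells must be non-negative numbers")
  rownames(tpm) <- df$candidate_id
  star <- NULL
  if (!is.null(star_path)) {
    sf <- read.delim(star_path, header = TRUE, sep = "\t", comment.char = "#",
                     check.names = FALSE, stringsAsFactors = FALSE)
    star <- as.matrix(sf[, setdiff(colnames(sf), "candidate_id"), drop = FALSE]) > 0
    rownames(star) <- sf$candidate_id
    star <- star[rownames(tpm), colnames(tpm), drop = FALSE]
  }
  list(info = df[, need], tpm = tpm, star = star)
}
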