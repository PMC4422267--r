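#' Read a raw small-RNA count matrix
#'
#' Reads a tab-separated count table: header row of library identifiers, first
#' column the entity (miRNA/tag) identifier, remaining cells non-negative
#' integer read counts. Lines starting with \code{#} are ignored. Validation is
#' strict: a non-integer cell, a duplicated entity identifier or a malformed
#' header is an error naming the offending row/column — missing data are never
#' silently coerced to zero, because a zero has meaning downstream (it is the
#' only value the 0.01-TPM floor replaces).
#'
#' @param path path to a TSV file.
#' @return integer matrix, entities in rows (rownames), libraries in columns
#'   (colnames), in file order.
#' @seealso [read_expression_matrix()] for real-valued (TPM) tables.
#' @export
read_count_matrix <- function(path) {
  raw <- read_entity_table(path)
  mat <- raw$values
  bad <- !grepl("^[0-9]+$", mat)
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(mat))
    abort(sprintf(
      "non-integer count '%s' at entity '%s', library '%s' in %s",
      mat[idx], raw$entity_ids[rc[1L]], raw$library_ids[rc[2L]], path),
      class = "spikefill_parse_error")
  }
  out <- matrix(as.integer(mat), nrow = nrow(mat),
                dimnames = list(raw$entity_ids, raw$library_ids))
  out
}

#' Read a real-valued expression matrix (TPM)
#'
#' Same dialect as [read_count_matrix()] but cells are non-negative reals,
#' e.g. a normalized TPM table such as the packaged novel-miRNA fixture.
#'
#' @inheritParams read_count_matrix
#' @return numeric matrix with entity rownames and library colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- read_entity_table(path)
  mat <- raw$values
  vals <- suppressWarnings(as.numeric(mat))
  bad <- is.na(vals) | vals < 0
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(mat))
    abort(sprintf(
      "invalid expression value '%s' at entity '%s', library '%s' in %s",
      mat[idx], raw$entity_ids[rc[1L]], raw$library_ids[rc[2L]], path),
      class = "spikefill_parse_error")
  }
  matrix(vals, nrow = nrow(mat),
         dimnames = list(raw$entity_ids, raw$library_ids))
}

# shared strict TSV reader: header + entity id column, all cells kept as text
read_entity_table <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path, class = "spikefill_parse_error")
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    abort("malformed header in ", path,
          ": need an entity-id column plus at least one library column",
          class = "spikefill_parse_error")
  }
  lib_ids <- colnames(df)[-1L]
  if (anyDuplicated(lib_ids)) {
    abort("duplicate library id in header of ", path, ": ",
          lib_ids[duplicated(lib_ids)][1L], class = "spikefill_parse_error")
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    abort("duplicate entity id in ", path, ": ", ids[duplicated(ids)][1L],
          class = "spikefill_parse_error")
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (any(is.na(vals)) || any(vals == "")) {
    idx <- which(is.na(vals) | vals == "")[1L]
    rc <- arrayInd(idx, dim(vals))
    abort(sprintf("missing cell at entity '%s', library '%s' in %s",
                  ids[rc[1L]], lib_ids[rc[2L]], path),
          class = "spikefill_parse_error")
  }
  list(entity_ids = ids, library_ids = lib_ids, values = vals)
}

#' Read library metadata
#'
#' One record per sequencing library with its condition (\code{superior} or
#' \code{inferior}), developmental stage in days after flowering, and the
#' library's total clean reads — the denominator for TPM normalization and the
#' \eqn{N_1, N_2} totals of the exact two-library test. Accepts TSV (columns
#' \code{library_id}, \code{condition}, \code{stage_daf},
#' \code{total_clean_reads}) or a JSON array of records; the format is chosen
#' by file extension. Records are returned sorted by condition then stage.
#'
#' @param path path to a TSV or JSON metadata file.
#' @return data.frame with columns \code{library_id} (character),
#'   \code{condition} (character), \code{stage_daf} (integer),
#'   \code{total_clean_reads} (double).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path, class = "spikefill_parse_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
  }
  validate_metadata(df)
}

#' Validate a library metadata table
#'
#' @param df data.frame of library records.
#' @return the validated data.frame, sorted by condition then stage.
#' @export
validate_metadata <- function(df) {
  need <- c("library_id", "condition", "stage_daf", "total_clean_reads")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) abort("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$library_id <- as.character(df$library_id)
  if (anyDuplicated(df$library_id)) {
    abort("duplicate library_id: ", df$library_id[duplicated(df$library_id)][1L])
  }
  bad_cond <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad_cond)) {
    abort("unknown condition '", bad_cond[1L], "' (expected superior/inferior)")
  }
  if (any(is.na(df$stage_daf)) || any(df$stage_daf <= 0) ||
      any(df$stage_daf != as.integer(df$stage_daf))) {
    abort("stage_daf must be positive integers")
  }
  df$stage_daf <- as.integer(df$stage_daf)
  if (any(is.na(df$total_clean_reads)) || any(df$total_clean_reads <= 0)) {
    abort("total_clean_reads must be positive")
  }
  df <- df[order(match(df$condition, CONDITIONS), df$stage_daf), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a result table to TSV
#'
#' Writes any result data.frame as a tab-separated file with a stable column
#' order and doubles rendered to 6 significant digits, so tables round-trip
#' losslessly at that precision. An empty table yields a header-only file.
#'
#' @param records data.frame of results.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6L)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) abort("unwritable path (no such directory): ", dir)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a numeric matrix (counts or TPM) to TSV
#'
#' Inverse of [read_count_matrix()] / [read_expression_matrix()]: first column
#' \code{entity_id}, then one column per library. Doubles are written to 6
#' significant digits.
#'
#' @param mat matrix with entity rownames and library colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(entity_id = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- if (is.double(mat)) signif(mat, 6L) else mat
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequence sets keyed by annotation class
#'
#' Reads one FASTA file per small-RNA class (rRNA, tRNA, snoRNA, snRNA, miRNA,
#' ...) into a named list of upper-case sequence vectors, for use with
#' [classify_reads()].
#'
#' @param paths named character vector: class name -> FASTA path.
#' @return named list of character vectors of sequences.
#' @export
read_class_sets <- function(paths) {
  stopifnot(is.character(paths), !is.null(names(paths)))
  lapply(as.list(paths), function(p) {
    seqs <- Biostrings::readDNAStringSet(p)
    toupper(as.character(seqs))
  })
}
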