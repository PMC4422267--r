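# Shared fixture builders: everything is generated in code at test time.

# the study design: 2 conditions x 5 stages, one library each
make_meta <- function(total = 1.5e5) {
  data.frame(
    library_id = c(paste0("S", c(10, 15, 21, 27, 35)),
                   paste0("I", c(10, 15, 21, 27, 35))),
    condition = rep(c("superior", "inferior"), each = 5L),
    stage_daf = rep(c(10L, 15L, 21L, 27L, 35L), 2L),
    total_clean_reads = rep(total, 10L),
    stringsAsFactors = FALSE)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

table1_path <- function() {
  system.file("extdata", "table1_novel_mirnas.tsv", package = "spikefill")
}
table1_tpm <- function() read_novel_candidates(table1_path())$tpm
table1_star_path <- function() {
  system.file("extdata", "table1_star_synthetic.tsv", package = "spikefill")
}

# exact-rational oracle for the two-library statistic (stdlib Python);
# returns data.frame N1, N2, x, y, p
exact_ac_oracle <- function(pairs, xmax, ymax) {
  spec <- paste(vapply(pairs, function(p) paste(sprintf("%.0f", p), collapse = ","), ""),
                collapse = ";")
  out <- tempfile(fileext = ".tsv")
  status <- system2("python",
                    c(shQuote(test_path("exact-ac-oracle.py")),
                      shQuote(spec), xmax, ymax),
                    stdout = out)
  stopifnot(status == 0L)
  read.delim(out)
}
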