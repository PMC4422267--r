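test_that("TPM normalization is count * 1e6 / total clean reads", {
  counts <- matrix(c(100L, 0L, 7L, 50L), nrow = 2L,
                   dimnames = list(c("a", "b"), c("S10", "I10")))
  meta <- data.frame(library_id = c("S10", "I10"),
                     condition = c("superior", "inferior"),
                     stage_daf = c(10L, 10L),
                     total_clean_reads = c(1e7, 2e6))
  tpm <- tpm_normalize(counts, meta)
  expect_equal(tpm["a", "S10"], 10)       # 100 / 1e7 * 1e6
  expect_equal(tpm["b", "S10"], 0)        # zero stays zero; floor is separate
  expect_equal(tpm["b", "I10"], 25)
  # column linearity: sum(TPM) = 1e6 * colsum / total
  expect_equal(colSums(tpm),
               1e6 * colSums(counts) / c(S10 = 1e7, I10 = 2e6))
  expect_error(tpm_normalize(counts, meta[1L, ]), "no metadata for library")
})

test_that("TPM is invariant to scaling counts and totals together", {
  set.seed(7)
  counts <- matrix(rpois(40L, 50), nrow = 10L,
                   dimnames = list(paste0("m", 1:10),
                                   c("S10", "S15", "I10", "I15")))
  meta <- data.frame(library_id = colnames(counts),
                     condition = rep(c("superior", "inferior"), each = 2L),
                     stage_daf = rep(c(10L, 15L), 2L),
                     total_clean_reads = c(1e5, 1.2e5, 1.4e5, 1.6e5))
  meta3 <- meta; meta3$total_clean_reads <- meta3$total_clean_reads * 3
  expect_equal(tpm_normalize(counts, meta), tpm_normalize(counts * 3L, meta3))
})

test_that("the floor replaces only exact zeros and is idempotent", {
  m <- matrix(c(0, 0.005, 12, 0), nrow = 2L,
              dimnames = list(c("a", "b"), c("S10", "I10")))
  f <- apply_floor(m)
  expect_equal(f["a", "S10"], 0.01)
  expect_equal(f["b", "S10"], 0.005)     # nonzero below floor: untouched
  expect_equal(f["a", "I10"], 12)        # above floor: untouched
  expect_equal(f["b", "I10"], 0.01)
  expect_identical(apply_floor(f), f)    # idempotent
  expect_error(apply_floor(m, floor = -1), "positive")
})

test_that("the abundance filter keeps entities strictly above threshold somewhere", {
  # miRn2's published profile must survive; an all-floor row must not
  tab <- table1_tpm()
  expr <- rbind(tab["miRn2", , drop = FALSE],
                matrix(0.01, 1L, ncol(tab), dimnames = list("floor_row", colnames(tab))),
                matrix(c(10, rep(0, ncol(tab) - 1L)), 1L,
                       dimnames = list("exactly_ten", colnames(tab))))
  res <- abundance_filter(expr)
  expect_true("miRn2" %in% rownames(res$kept))
  expect_true("floor_row" %in% res$dropped_ids)
  expect_true("exactly_ten" %in% res$dropped_ids)  # strict "higher than 10"
  # exhaustive and disjoint partition
  expect_setequal(c(rownames(res$kept), res$dropped_ids), rownames(expr))
  expect_length(intersect(rownames(res$kept), res$dropped_ids), 0L)
  expect_error(abundance_filter(expr, threshold = 0.005), "must exceed")
})

test_that("the kept set is invariant to flooring", {
  set.seed(11)
  expr <- matrix(rexp(60L, rate = 1 / 8), nrow = 12L,
                 dimnames = list(paste0("m", 1:12), paste0("L", 1:5)))
  expr[sample(length(expr), 15L)] <- 0
  raw <- abundance_filter(expr)
  floored <- abundance_filter(apply_floor(expr))
  expect_identical(rownames(raw$kept), rownames(floored$kept))
})

test_that("length distributions are per-library and pooled fractions", {
  h <- matrix(c(50L, 50L, 10L, 90L), nrow = 2L,
              dimnames = list(c(21, 24), c("S10", "I10")))
  ld <- length_distribution(h)
  expect_equal(ld$per_library[, "S10"], c("21" = 0.5, "24" = 0.5))
  expect_equal(unname(ld$pooled), c(60, 140) / 200)
  # degenerate: a single length
  one <- matrix(100L, 1L, 1L, dimnames = list(24, "S10"))
  expect_equal(length_distribution(one)$per_library[1L, 1L], 1)
  empty <- matrix(0L, 2L, 1L, dimnames = list(c(21, 24), "S10"))
  expect_error(length_distribution(empty), "empty histogram")
  badlen <- matrix(1L, 1L, 1L, dimnames = list(35, "S10"))
  expect_error(length_distribution(badlen), "18-30")
})

test_that("generated length histograms reproduce the 24-nt dominance", {
  cfg <- simulation_config(n_mirnas = 10L, seed = 5L)
  sim <- simulate_counts(cfg)
  ld <- length_distribution(sim$length_hist)
  w <- sim$truth$length_weights
  expect_gt(ld$pooled[["24"]], ld$pooled[["21"]])
  # multinomial law of large numbers: pooled fractions near the weights
  expect_equal(unname(ld$pooled[c("24", "21")]), unname(w[c("24", "21")]),
               tolerance = 0.01)
})

test_that("read classification is priority-ordered, exact and count-conserving", {
  sets <- list(rRNA = c("ACGTACGT"), tRNA = c("ACGTACGT", "TTTTCCCC"),
               miRNA = c("TGGATACT"))
  reads <- c("ACGTACGT", "ACGTACGT", "TTTTCCCC", "TGGATACT", "GGGGGGGG")
  cc <- classify_reads(reads, sets)
  expect_equal(cc[["rRNA"]], 2L)          # wins over tRNA by priority
  expect_equal(cc[["tRNA"]], 1L)
  expect_equal(cc[["miRNA"]], 1L)
  expect_equal(cc[["unannotated"]], 1L)
  expect_equal(sum(cc), length(reads))    # conservation
  expect_warning(res <- classify_reads(reads, list()), "unannotated")
  expect_equal(unname(res), length(reads))
})
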