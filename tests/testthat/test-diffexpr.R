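# Worked values frozen from the exact-rational oracle (exact-ac-oracle.py):
#   p(30 | 10) with N1 = 1e6, N2 = 2e6  ->  2.4954587006106706e-02
ORACLE_P_10_30 <- 2.4954587006106706e-02

test_that("the exact statistic reproduces closed-form and oracle values", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)          # 2^-1
  expect_equal(ac_probability(2, 1, 1e6, 1e6), 3 / 16)       # 3!/(2!1!) 2^-4
  expect_equal(ac_probability(10, 30, 1e6, 2e6), ORACLE_P_10_30,
               tolerance = 1e-12)
  expect_error(ac_probability(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(ac_probability(1, 0, 0, 1e6), "positive")
})

test_that("the statistic equals the negative-binomial pmf (independent cross-check)", {
  grid <- expand.grid(x = c(0L, 1L, 7L, 40L, 100L), y = c(0L, 3L, 25L, 90L),
                      N1 = c(1e4, 1e6), N2 = c(1e4, 2e6))
  mine <- ac_probability(grid$x, grid$y, grid$N1, grid$N2)
  ref <- dnbinom(grid$y, size = grid$x + 1, prob = grid$N1 / (grid$N1 + grid$N2))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("tail p-values match their definitions and the doubling convention", {
  pv <- ac_pvalue(5, 0, 1e6, 1e6)
  expect_equal(pv$p_lower, 2^-6)           # single term p(0|5)
  expect_equal(pv$p_two_sided, 0.03125)    # doubled smaller tail
  expect_equal(pv$p_upper, 1)              # upper tail includes everything

  # tails include the observed point: p_lower + p_upper = 1 + p(y|x)
  for (y in c(0L, 2L, 9L, 31L)) {
    pv <- ac_pvalue(7, y, 1e6, 2e6)
    expect_equal(pv$p_lower + pv$p_upper,
                 1 + ac_probability(7, y, 1e6, 2e6), tolerance = 1e-9)
  }

  # against pnbinom on both tails, including deep tails
  cases <- expand.grid(x = c(0L, 4L, 60L), y = c(0L, 10L, 200L))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    pv <- ac_pvalue(x, y, 1e6, 2e6)
    pr <- 1e6 / 3e6
    expect_equal(pv$p_lower, pnbinom(y, size = x + 1, prob = pr),
                 tolerance = 1e-10)
    up <- 1 - pnbinom(y - 1, size = x + 1, prob = pr)
    if (up > 1e-12) expect_equal(pv$p_upper, up, tolerance = 1e-8)
  }
})

test_that("with equal totals the statistic is symmetric and tails are monotone", {
  # pointwise symmetry p(y|x) = p(x|y); the tail p-values themselves condition
  # on the first library's count, so only the point probability swaps exactly
  for (pair in list(c(0L, 0L), c(3L, 8L), c(20L, 5L))) {
    expect_equal(ac_probability(pair[1L], pair[2L], 1e6, 1e6),
                 ac_probability(pair[2L], pair[1L], 1e6, 1e6))
  }
  # at deep counts the two-sided p-value becomes swap-stable
  a <- ac_pvalue(400L, 470L, 1e6, 1e6)
  b <- ac_pvalue(470L, 400L, 1e6, 1e6)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 0.05)
  # x = y with equal totals: two-sided p >= point probability
  pv <- ac_pvalue(12, 12, 1e6, 1e6)
  expect_gte(pv$p_two_sided, ac_probability(12, 12, 1e6, 1e6))
  # p_upper non-increasing in y
  ups <- ac_pvalue(rep(10L, 40L), 0:39, 1e6, 2e6)$p_upper
  expect_true(all(diff(ups) <= 1e-12))
})

test_that("fold changes floor zeros and take the binary log of inferior/superior", {
  expect_equal(log2_fold_change(20, 10), data.frame(ratio = 2, log2_fc = 1))
  expect_equal(log2_fold_change(10, 10)$log2_fc, 0)
  z <- log2_fold_change(0, 10)
  expect_equal(z$ratio, 0.001)
  expect_equal(z$log2_fc, log2(0.001), tolerance = 1e-6)   # ~ -9.966
  expect_error(log2_fold_change(-1, 10), "non-negative")
})

test_that("DE classification applies the fold-change gate and p-value bands", {
  expect_equal(classify_de(1.5, 0.03), "differential")
  expect_equal(classify_de(-2.0, 0.004), "significant")
  expect_equal(classify_de(0.5, 0.001), "not_de")   # gate fails despite tiny p
  # boundaries: closed [0.01, 0.05] for differential, strict < 0.01 beyond
  expect_equal(classify_de(c(1.1, 1.1, 1.1, 1), c(0.01, 0.05, 0.0099, 0.001)),
               c("differential", "differential", "significant", "not_de"))
  expect_error(classify_de(1, 1.5), "0, 1")
})

test_that("stage comparison pairs libraries, tests counts, folds TPM", {
  meta <- make_meta(total = 1e5)
  counts <- matrix(5L, nrow = 2L, ncol = 10L,
                   dimnames = list(c("flat", "shift"), meta$library_id))
  counts["shift", meta$condition == "inferior"] <- 80L
  recs <- stage_comparison(counts, meta)
  expect_equal(nrow(recs), 10L)                       # 2 entities x 5 stages
  flat <- recs[recs$entity_id == "flat", ]
  expect_true(all(flat$log2_fc == 0))
  expect_true(all(flat$label == "not_de"))
  shift <- recs[recs$entity_id == "shift", ]
  expect_equal(shift$log2_fc, rep(log2(16), 5L))
  expect_true(all(shift$label == "significant"))
  # an unmatched stage aborts: drop the 10-DAF inferior library everywhere
  expect_error(stage_comparison(counts[, meta$library_id != "I10"],
                                meta[meta$library_id != "I10", ]),
               "exactly one superior")
})

test_that("the paired t-test matches the closed form and flags degeneracy", {
  # differences [1,2,3,1,2]: t = 1.8 / sqrt(0.7/5) = 4.8107, p = 0.008581
  inf <- c(10, 11, 12, 13, 14)
  sup <- inf + c(1, 2, 3, 1, 2)
  res <- paired_ttest(sup, inf)
  expect_equal(res$n_pairs, 5L)
  expect_equal(res$t_statistic, 4.810702354, tolerance = 1e-8)
  expect_equal(res$p_value, 0.008580918722, tolerance = 1e-8)
  expect_equal(res$direction, "superior_higher")

  same <- paired_ttest(inf, inf)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  const <- paired_ttest(inf + 2, inf)   # zero-variance nonzero-mean differences
  expect_equal(const$p_value, 0)
  expect_true(const$zero_variance)
  expect_equal(const$direction, "superior_higher")

  jitter <- paired_ttest(inf + c(2.0, 2.1, 1.9, 2.0, 2.1), inf)
  expect_equal(jitter$direction, "superior_higher")
  expect_error(paired_ttest(1, numeric(0)), "equal length")
})

test_that("DE summaries reproduce proportions from their own records", {
  # 109 DE at one stage, 103 of them higher in superior (fc < 0)
  recs <- data.frame(
    entity_id = sprintf("m%03d", 1:160),
    stage_daf = 15L,
    log2_fc = c(rep(-1.5, 103L), rep(1.5, 6L), rep(0.2, 51L)),
    p_two_sided = c(rep(0.001, 103L), rep(0.03, 6L), rep(0.6, 51L)))
  recs$label <- classify_de(recs$log2_fc, recs$p_two_sided)
  s <- summarize_de(recs)
  expect_equal(s$per_stage$n_de, 109L)
  expect_equal(s$per_stage$pct_higher_superior, 94.50)
  expect_equal(s$per_stage$n_significant, 103L)
  expect_equal(s$per_stage$n_differential, 6L)

  none <- recs; none$label <- "not_de"
  s0 <- summarize_de(none)
  expect_equal(s0$per_stage$n_de, 0L)
  expect_equal(s0$per_stage$pct_higher_superior, 0)

  # overall block from paired tests: 19 + 11 directional out of 160
  paired <- data.frame(
    entity_id = recs$entity_id,
    direction = c(rep("superior_higher", 19L), rep("inferior_higher", 11L),
                  rep("none", 130L)))
  s2 <- summarize_de(recs, paired)
  expect_equal(s2$overall$pct_consistent_superior, 11.88)
  expect_equal(s2$overall$pct_consistent_inferior, 6.88)
})
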