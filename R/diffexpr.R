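#' Exact two-library tag-count probability
#'
#' Probability of observing \code{y} tags for an entity in library 2 given
#' \code{x} tags in library 1, when the libraries have \eqn{N_1} and \eqn{N_2}
#' total clean tags (an Audic--Claverie-type statistic):
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!}
#'   \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}}
#' For fixed \code{x} this is a probability distribution over \eqn{y = 0, 1,
#' \ldots} (it is the negative-binomial pmf with size \eqn{x+1} and success
#' probability \eqn{N_1/(N_1+N_2)}, which [ac_pvalue()] tests exploit as an
#' independent cross-check). Evaluation is in log space via \code{lgamma} —
#' the factorials overflow double precision well before \eqn{x+y} reaches the
#' thousands that deep libraries produce.
#'
#' By convention library 1 is the superior-spikelet library and library 2 the
#' inferior one, matching the fold-change ratio R = inferior/superior.
#'
#' @param x,y non-negative integer tag counts (vectorized).
#' @param N1,N2 positive library totals (total clean tags).
#' @param log if \code{TRUE} return the log probability.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
ac_probability <- function(x, y, N1, N2, log = FALSE) {
  check_ac_args(x, y, N1, N2)
  lp <- y * (base::log(N2) - base::log(N1)) +
    lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(N2 / N1)
  if (log) lp else exp(lp)
}

check_ac_args <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    abort("x and y must be non-negative integers")
  }
  if (any(N1 <= 0) || any(N2 <= 0)) {
    abort("library totals N1, N2 must be positive")
  }
  invisible(TRUE)
}

#' Tail p-values of the exact two-library test
#'
#' Cumulative tails of [ac_probability()] at the observed count:
#' \code{p_lower} \eqn{= \sum_{k=0}^{y} p(k|x)} and \code{p_upper}
#' \eqn{= \sum_{k=y}^{\infty} p(k|x)}; both tails include the observed point,
#' so \code{p_lower + p_upper = 1 + p(y|x)}. The two-sided p-value doubles the
#' smaller tail, capped at 1. Whichever tail is smaller is accumulated
#' directly by a stable term recurrence (never as one minus a near-unit sum),
#' with the infinite upper tail truncated under a geometric bound once terms
#' decay, so both tails are accurate even when far below machine epsilon of 1.
#'
#' @inheritParams ac_probability
#' @return data.frame with columns \code{p_lower}, \code{p_upper},
#'   \code{p_two_sided} (one row per input).
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  check_ac_args(x, y, N1, N2)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  res <- vapply(seq_len(n), function(i) ac_pvalue_1(x[i], y[i], N1[i], N2[i]),
                numeric(3L))
  out <- as.data.frame(t(res))
  names(out) <- c("p_lower", "p_upper", "p_two_sided")
  out
}

# scalar tails; r = P(next tag falls in library 2) = N2/(N1+N2)
ac_pvalue_1 <- function(x, y, N1, N2) {
  r <- N2 / (N1 + N2)
  mean_y <- (x + 1) * N2 / N1   # mean of the conditional distribution
  point <- ac_probability(x, y, N1, N2)
  if (y <= mean_y) {
    # lower tail is the short sum: accumulate p(0|x) .. p(y|x)
    p_lower <- ac_tail_sum(x, 0, y, N1, N2, r)
    p_upper <- 1 - p_lower + point
  } else {
    # upper tail is the short sum: accumulate p(y|x) .. until negligible
    p_upper <- ac_upper_tail(x, y, N1, N2, r)
    p_lower <- 1 - p_upper + point
  }
  p_lower <- min(max(p_lower, 0), 1)
  p_upper <- min(max(p_upper, 0), 1)
  c(p_lower, p_upper, min(1, 2 * min(p_lower, p_upper)))
}

# sum of p(k|x) for k in [from, to] using the ratio recurrence
# p(k+1|x)/p(k|x) = r * (x+k+1)/(k+1)
ac_tail_sum <- function(x, from, to, N1, N2, r) {
  term <- ac_probability(x, from, N1, N2)
  total <- term
  k <- from
  while (k < to) {
    term <- term * r * (x + k + 1) / (k + 1)
    total <- total + term
    k <- k + 1
  }
  total
}

# sum of p(k|x) for k >= y; truncated when the geometric bound on the
# remainder drops below 1e-17 of the accumulated mass
ac_upper_tail <- function(x, y, N1, N2, r) {
  term <- ac_probability(x, y, N1, N2)
  total <- term
  k <- y
  repeat {
    ratio <- r * (x + k + 1) / (k + 1)
    term <- term * ratio
    total <- total + term
    k <- k + 1
    if (ratio < 1) {
      bound <- term * ratio / (1 - ratio)
      if (bound < 1e-17 * total || bound < 1e-320) break
    }
    if (k > y + 1e7) abort("upper tail failed to converge")  # unreachable guard
  }
  total
}

#' Expression ratio and log2 fold change
#'
#' The ratio R of the normalized expression in inferior spikelets to that in
#' superior spikelets at the same stage; the fold change is its binary
#' logarithm. Exact zeros are replaced by the floor (default 0.01 TPM) before
#' the ratio so the logarithm is always finite.
#'
#' @param tpm_inferior,tpm_superior non-negative TPM values (vectorized).
#' @param floor positive replacement for exact zeros.
#' @return data.frame with columns \code{ratio} and \code{log2_fc}.
#' @export
log2_fold_change <- function(tpm_inferior, tpm_superior, floor = 0.01) {
  if (any(tpm_inferior < 0) || any(tpm_superior < 0)) {
    abort("TPM values must be non-negative")
  }
  if (floor <= 0) abort("floor must be positive")
  inf_f <- ifelse(tpm_inferior == 0, floor, tpm_inferior)
  sup_f <- ifelse(tpm_superior == 0, floor, tpm_superior)
  ratio <- inf_f / sup_f
  data.frame(ratio = ratio, log2_fc = log2(ratio))
}

#' Classify a miRNA-stage comparison
#'
#' A comparison is \code{differential} when the absolute log2 fold change
#' exceeds 1 (more than two-fold) and the two-sided p-value lies in
#' \[0.01, 0.05\]; it is \code{significant} when the fold-change gate passes
#' and p < 0.01; anything else is \code{not_de}. The fold-change gate is
#' strict (|fc| > 1); the p-interval is closed at 0.01, so the boundary
#' belongs to \code{differential}.
#'
#' @param log2_fc log2 fold change(s).
#' @param p_two_sided two-sided p-value(s) in \[0, 1\].
#' @return character vector of labels in
#'   \code{c("not_de", "differential", "significant")}.
#' @export
classify_de <- function(log2_fc, p_two_sided) {
  if (any(p_two_sided < 0 | p_two_sided > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  gate <- abs(log2_fc) > 1
  out <- rep("not_de", length(log2_fc))
  out[gate & p_two_sided >= 0.01 & p_two_sided <= 0.05] <- "differential"
  out[gate & p_two_sided < 0.01] <- "significant"
  out
}

#' Superior-vs-inferior comparison at every stage
#'
#' For each grain-filling stage with exactly one superior and one inferior
#' library, computes per entity the exact-test tails on the raw counts (with
#' each library's total clean tags) and the fold change on floored TPM, then
#' classifies. The test consumes raw counts — the scale on which the exact
#' statistic is defined — while the fold change consumes normalized floored
#' expression, keeping each formula on its own scale.
#'
#' @param counts integer raw-count matrix (entities x libraries).
#' @param meta library metadata (one superior + one inferior per stage).
#' @param expr optional floored TPM matrix; computed from \code{counts} and
#'   \code{meta} with [tpm_normalize()] + [apply_floor()] when omitted.
#' @param floor zero floor used for fold changes (and flooring when
#'   \code{expr} is computed here).
#' @return data.frame of DE records: \code{entity_id}, \code{stage_daf},
#'   \code{tpm_superior}, \code{tpm_inferior}, \code{ratio}, \code{log2_fc},
#'   \code{p_lower}, \code{p_upper}, \code{p_two_sided}, \code{label}.
#' @export
stage_comparison <- function(counts, meta, expr = NULL, floor = 0.01) {
  meta <- validate_metadata(meta)
  if (is.null(expr)) {
    expr <- apply_floor(tpm_normalize(counts, meta), floor)
  }
  stages <- sort(unique(meta$stage_daf))
  recs <- lapply(stages, function(st) {
    sup <- meta[meta$condition == "superior" & meta$stage_daf == st, ]
    inf <- meta[meta$condition == "inferior" & meta$stage_daf == st, ]
    if (nrow(sup) != 1L || nrow(inf) != 1L) {
      abort("stage ", st, " DAF needs exactly one superior and one inferior library")
    }
    x <- counts[, sup$library_id]
    y <- counts[, inf$library_id]
    pv <- ac_pvalue(x, y, sup$total_clean_reads, inf$total_clean_reads)
    fc <- log2_fold_change(expr[, inf$library_id], expr[, sup$library_id],
                           floor = floor)
    data.frame(entity_id = rownames(counts),
               stage_daf = st,
               tpm_superior = expr[, sup$library_id],
               tpm_inferior = expr[, inf$library_id],
               ratio = fc$ratio,
               log2_fc = fc$log2_fc,
               p_lower = pv$p_lower,
               p_upper = pv$p_upper,
               p_two_sided = pv$p_two_sided,
               label = classify_de(fc$log2_fc, pv$p_two_sided),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Paired t-test across grain-filling stages
#'
#' Two-tailed paired t-test of an entity's superior vs. inferior expression
#' series aligned by stage (n pairs = number of stages, df = n - 1), as used
#' to call miRNAs consistently higher in one spikelet type across the whole
#' filling course. The regular path delegates to [stats::t.test()]; the
#' degenerate cases it refuses are resolved explicitly: all differences zero
#' gives t = 0, p = 1; zero-variance differences with nonzero mean give p = 0
#' with \code{zero_variance = TRUE}. A direction is assigned only when
#' p < 0.05.
#'
#' @param superior_series,inferior_series numeric vectors of equal length
#'   (>= 2), aligned by stage.
#' @return data.frame (one row): \code{n_pairs}, \code{t_statistic},
#'   \code{p_value}, \code{direction} (\code{superior_higher},
#'   \code{inferior_higher} or \code{none}), \code{zero_variance}.
#' @export
paired_ttest <- function(superior_series, inferior_series) {
  n <- length(superior_series)
  if (n < 2L || length(inferior_series) != n) {
    abort("series must have equal length >= 2")
  }
  d <- superior_series - inferior_series
  zero_var <- isTRUE(all.equal(var(d), 0)) || var(d) == 0
  if (zero_var) {
    if (all(d == 0)) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    ht <- stats::t.test(superior_series, inferior_series, paired = TRUE,
                        alternative = "two.sided")
    tstat <- unname(ht$statistic); p <- ht$p.value
  }
  direction <- "none"
  if (p < 0.05 && mean(d) > 0) direction <- "superior_higher"
  if (p < 0.05 && mean(d) < 0) direction <- "inferior_higher"
  data.frame(n_pairs = n, t_statistic = tstat, p_value = p,
             direction = direction, zero_variance = zero_var,
             stringsAsFactors = FALSE)
}

#' Summarize differential-expression calls
#'
#' Per stage: how many entities are differentially expressed (the
#' \code{differential} and \code{significant} classes together, also reported
#' separately), how many of those sit higher in superior spikelets (fold
#' change < 0, since R = inferior/superior) vs. higher in inferior, with
#' percentages to two decimals. Globally, from per-entity paired tests: how
#' many entities are consistently higher in one condition across all stages.
#'
#' @param records DE records from [stage_comparison()].
#' @param per_entity_tests optional data.frame of paired-test results with an
#'   \code{entity_id} column and the columns of [paired_ttest()].
#' @return list with \code{per_stage} (data.frame) and \code{overall}
#'   (data.frame or NULL when no paired tests given).
#' @export
summarize_de <- function(records, per_entity_tests = NULL) {
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2L) else 0
  per_stage <- do.call(rbind, lapply(sort(unique(records$stage_daf)), function(st) {
    r <- records[records$stage_daf == st, ]
    de <- r[r$label != "not_de", ]
    n_de <- nrow(de)
    n_sup <- sum(de$log2_fc < 0)
    n_inf <- sum(de$log2_fc > 0)
    data.frame(stage_daf = st,
               n_tested = nrow(r),
               n_de = n_de,
               n_differential = sum(r$label == "differential"),
               n_significant = sum(r$label == "significant"),
               n_higher_superior = n_sup,
               n_higher_inferior = n_inf,
               pct_higher_superior = pct(n_sup, n_de),
               pct_higher_inferior = pct(n_inf, n_de))
  }))
  overall <- NULL
  if (!is.null(per_entity_tests)) {
    n_tot <- nrow(per_entity_tests)
    n_sup <- sum(per_entity_tests$direction == "superior_higher")
    n_inf <- sum(per_entity_tests$direction == "inferior_higher")
    overall <- data.frame(n_entities = n_tot,
                          n_consistent_superior = n_sup,
                          n_consistent_inferior = n_inf,
                          pct_consistent_superior = pct(n_sup, n_tot),
                          pct_consistent_inferior = pct(n_inf, n_tot))
  }
  list(per_stage = per_stage, overall = overall)
}
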