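#' Configuration for the synthetic spikelet experiment
#'
#' Builds a validated configuration for the generator, which emulates the
#' study design: two conditions (superior/inferior spikelets), five
#' grain-filling stages (10, 15, 21, 27, 35 DAF), one small-RNA library per
#' condition x stage. Defaults are fixed at the study's conditions, scaled to
#' desk size where noted:
#' \itemize{
#'   \item library sizes uniform on 1e5--2e5 clean reads, a ~1/100 scaling of
#'     the sequenced 10.6M--17.7M;
#'   \item \code{de_fraction = 0.30}: the study called 141 of 457 known
#'     miRNAs differentially expressed in at least one stage;
#'   \item \code{prob_higher_superior = 0.9}: ~94.5% of DE miRNAs were higher
#'     in superior spikelets;
#'   \item read-length weights with 24-nt at 58.28% and 21-nt at 18.30% of
#'     reads (the printed pooled proportions), the remainder spread over
#'     18--30 nt;
#'   \item logistic kinetics: superior K=22 mg, a=60, b=0.32/day
#'     (fast, early, asymmetric rate curve); inferior K=16 mg, a=35,
#'     b=0.12/day (slow, late, near-symmetric); weight noise 0.4 mg;
#'   \item baseline miRNA abundances lognormal, median 30 TPM with a heavy
#'     right tail (\code{meanlog = log(30)}, \code{sdlog = 1.5});
#'   \item negative-binomial counts with dispersion 0.05 (set 0 for Poisson,
#'     the exact test's own sampling model);
#'   \item target genes log-linearly anti-coupled to their miRNA with slope
#'     -1 and log2 noise sd 0.1.
#' }
#'
#' @param n_mirnas number of miRNA entities.
#' @param stage_daf sampling stages (days after flowering).
#' @param library_size_range min/max total clean reads per library.
#' @param de_fraction fraction of entities differentially expressed.
#' @param de_log2fc_range magnitude range of true log2 fold changes.
#' @param prob_higher_superior probability a DE entity is higher in superior
#'   spikelets (true log2 fc of inferior/superior negative).
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline TPM parameters.
#' @param length_weights named numeric vector of read-length weights
#'   (names = lengths in nt, 18--30); normalized internally.
#' @param star_fraction fraction of entities carrying miRNA* (star) reads.
#' @param kinetics_superior,kinetics_inferior named vectors c(K =, a =, b =).
#' @param weight_noise_sd Gaussian noise sd on grain weights (mg).
#' @param target_coupling_slope slope of log2(target) on log2(miRNA).
#' @param target_noise_sd log2-scale Gaussian noise sd for targets.
#' @param seed integer seed; mandatory, every stochastic call derives from it.
#' @return validated list of class \code{sim_config}.
#' @export
simulation_config <- function(n_mirnas = 300L,
                              stage_daf = c(10L, 15L, 21L, 27L, 35L),
                              library_size_range = c(1e5, 2e5),
                              de_fraction = 0.30,
                              de_log2fc_range = c(1, 3),
                              prob_higher_superior = 0.9,
                              dispersion = 0.05,
                              baseline_meanlog = log(30),
                              baseline_sdlog = 1.5,
                              length_weights = default_length_weights(),
                              star_fraction = 0.15,
                              kinetics_superior = c(K = 22, a = 60, b = 0.32),
                              kinetics_inferior = c(K = 16, a = 35, b = 0.12),
                              weight_noise_sd = 0.4,
                              target_coupling_slope = -1,
                              target_noise_sd = 0.1,
                              seed = NULL) {
  cfg <- list(n_mirnas = as.integer(n_mirnas), stage_daf = as.integer(stage_daf),
              library_size_range = library_size_range,
              de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
              prob_higher_superior = prob_higher_superior,
              dispersion = dispersion,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              length_weights = length_weights, star_fraction = star_fraction,
              kinetics_superior = kinetics_superior,
              kinetics_inferior = kinetics_inferior,
              weight_noise_sd = weight_noise_sd,
              target_coupling_slope = target_coupling_slope,
              target_noise_sd = target_noise_sd, seed = seed)
  validate_sim_config(cfg)
}

default_length_weights <- function() {
  lens <- 18:30
  w <- setNames(rep(0.02, length(lens)), lens)   # flat background
  w[["24"]] <- 0.5828
  w[["21"]] <- 0.1830
  w / sum(w)
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort("config field '", nm, "' must be a fraction in [0, 1]",
            class = "spikefill_config_error")
    }
  }
  if (cfg$n_mirnas < 1L) abort("n_mirnas must be >= 1", class = "spikefill_config_error")
  if (length(cfg$stage_daf) < 1L || any(cfg$stage_daf <= 0)) {
    abort("stage_daf must be positive", class = "spikefill_config_error")
  }
  if (length(cfg$library_size_range) != 2L ||
      cfg$library_size_range[1L] > cfg$library_size_range[2L] ||
      cfg$library_size_range[1L] <= 0) {
    abort("library_size_range must be an ordered positive pair",
          class = "spikefill_config_error")
  }
  chk_frac(cfg$de_fraction, "de_fraction")
  chk_frac(cfg$prob_higher_superior, "prob_higher_superior")
  chk_frac(cfg$star_fraction, "star_fraction")
  if (diff(cfg$de_log2fc_range) < 0 || cfg$de_log2fc_range[1L] < 0) {
    abort("de_log2fc_range must be an ordered non-negative pair",
          class = "spikefill_config_error")
  }
  if (cfg$dispersion < 0) abort("dispersion must be >= 0", class = "spikefill_config_error")
  if (cfg$weight_noise_sd < 0) {
    abort("weight_noise_sd must be >= 0", class = "spikefill_config_error")
  }
  for (nm in c("kinetics_superior", "kinetics_inferior")) {
    p <- cfg[[nm]]
    if (!all(c("K", "a", "b") %in% names(p)) || any(p[c("K", "a", "b")] <= 0)) {
      abort(nm, " must be a named positive vector c(K=, a=, b=)",
            class = "spikefill_config_error")
    }
  }
  if (is.null(cfg$seed)) {
    abort("seed is mandatory for the generator", class = "spikefill_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

lib_id <- function(condition, stage) {
  paste0(ifelse(condition == "superior", "S", "I"), stage)
}

#' Simulate a two-condition, five-stage small-RNA count experiment
#'
#' Draws per-miRNA baseline abundances from a lognormal (TPM scale), marks a
#' \code{de_fraction} of entities as truly differentially expressed with log2
#' fold changes (inferior over superior) of magnitude uniform in
#' \code{de_log2fc_range} — negative with probability
#' \code{prob_higher_superior} — applied at every stage, then draws raw
#' counts per library negative-binomially (Poisson when dispersion is 0)
#' around \code{TPM * 1e-6 * library_size}. Also draws per-library
#' read-length histograms from the configured length weights and flags a
#' \code{star_fraction} of entities with miRNA* (star) evidence in 1--3
#' random libraries. Identical seeds give identical output.
#'
#' @param cfg a \code{sim_config}.
#' @return list: \code{counts} (integer matrix), \code{meta} (metadata
#'   data.frame), \code{length_hist} (lengths x libraries matrix),
#'   \code{star} (logical entities x libraries matrix), \code{truth} (list:
#'   \code{baseline_tpm}, \code{de_truth} data.frame of per-entity/stage true
#'   log2 fc, \code{de_entities}, \code{star_entities},
#'   \code{length_weights}).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  stages <- cfg$stage_daf
  meta <- data.frame(
    library_id = c(lib_id("superior", stages), lib_id("inferior", stages)),
    condition = rep(CONDITIONS, each = length(stages)),
    stage_daf = rep(stages, 2L),
    total_clean_reads = round(runif(2L * length(stages),
                                    cfg$library_size_range[1L],
                                    cfg$library_size_range[2L])),
    stringsAsFactors = FALSE)

  ids <- sprintf("miR_%04d", seq_len(cfg$n_mirnas))
  baseline <- stats::rlnorm(cfg$n_mirnas, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- ids

  n_de <- round(cfg$de_fraction * cfg$n_mirnas)
  de_entities <- if (n_de > 0) sample(ids, n_de) else character(0)
  fc <- setNames(rep(0, cfg$n_mirnas), ids)
  if (n_de > 0) {
    mag <- runif(n_de, cfg$de_log2fc_range[1L], cfg$de_log2fc_range[2L])
    sgn <- ifelse(runif(n_de) < cfg$prob_higher_superior, -1, 1)
    fc[de_entities] <- mag * sgn
  }

  counts <- matrix(0L, cfg$n_mirnas, nrow(meta), dimnames = list(ids, meta$library_id))
  for (j in seq_len(nrow(meta))) {
    tpm <- baseline * if (meta$condition[j] == "inferior") 2^fc else 1
    mu <- tpm * 1e-6 * meta$total_clean_reads[j]
    counts[, j] <- if (cfg$dispersion > 0) {
      rnbinom(cfg$n_mirnas, mu = mu, size = 1 / cfg$dispersion)
    } else {
      rpois(cfg$n_mirnas, mu)
    }
  }

  lens <- as.integer(names(cfg$length_weights))
  lh <- vapply(seq_len(nrow(meta)), function(j) {
    as.vector(stats::rmultinom(1L, size = meta$total_clean_reads[j],
                               prob = cfg$length_weights))
  }, integer(length(lens)))
  dimnames(lh) <- list(lens, meta$library_id)

  n_star <- round(cfg$star_fraction * cfg$n_mirnas)
  star_entities <- if (n_star > 0) sample(ids, n_star) else character(0)
  star <- matrix(FALSE, cfg$n_mirnas, nrow(meta),
                 dimnames = list(ids, meta$library_id))
  for (e in star_entities) {
    star[e, sample(nrow(meta), sample(1:3, 1L))] <- TRUE
  }

  de_truth <- expand.grid(entity_id = ids, stage_daf = stages,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  de_truth$true_log2_fc <- fc[de_truth$entity_id]

  list(counts = counts, meta = meta, length_hist = lh, star = star,
       truth = list(baseline_tpm = baseline, de_truth = de_truth,
                    de_entities = sort(de_entities),
                    star_entities = sort(star_entities),
                    length_weights = cfg$length_weights))
}

#' Simulate grain-weight time series for both spikelet types
#'
#' Samples the logistic weight law at 5-day intervals from 5 to 45 DAF (nine
#' points, the study's sampling scheme) for the superior and inferior
#' parameter sets, adds Gaussian noise, and clamps negatives to zero (the
#' number of clamped points is recorded). The superior defaults have a higher
#' and earlier peak filling rate than the inferior defaults.
#'
#' @param cfg a \code{sim_config}.
#' @param times sampling days.
#' @return data.frame: \code{condition}, \code{daf}, \code{weight} (mg),
#'   \code{true_weight} (mg); attribute \code{n_clamped}.
#' @export
simulate_weights <- function(cfg, times = seq(5, 45, by = 5)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  out <- do.call(rbind, lapply(CONDITIONS, function(cond) {
    p <- cfg[[paste0("kinetics_", cond)]]
    y <- p[["K"]] / (1 + p[["a"]] * exp(-p[["b"]] * times))
    obs <- y + rnorm(length(times), 0, cfg$weight_noise_sd)
    data.frame(condition = cond, daf = times, weight = obs, true_weight = y,
               stringsAsFactors = FALSE)
  }))
  n_clamped <- sum(out$weight < 0)
  if (n_clamped > 0) warning(n_clamped, " negative weight(s) clamped to 0")
  out$weight <- pmax(out$weight, 0)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate target-gene series anti-coupled to miRNAs
#'
#' For each miRNA row of a (floored) TPM matrix, generates a target series
#' with \code{log2(target) = intercept + slope * log2(miRNA) + noise}; with
#' the default slope of -1 targets mirror their miRNA inversely, emulating
#' post-transcriptional repression readouts.
#'
#' @param cfg a \code{sim_config}.
#' @param mirna_expr floored TPM matrix (entities x libraries).
#' @return list: \code{targets} (matrix, rownames \code{<mirna>_target}) and
#'   \code{coupling} (data.frame of true slope/intercept per pair).
#' @export
simulate_targets <- function(cfg, mirna_expr) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(mirna_expr <= 0)) abort("mirna_expr must be floored (all cells > 0)")
  set.seed(cfg$seed + 2L)
  slope <- cfg$target_coupling_slope
  if (!is.finite(slope)) abort("target_coupling_slope must be finite")
  n <- nrow(mirna_expr)
  intercepts <- runif(n, 4, 10)
  noise <- matrix(rnorm(length(mirna_expr), 0, cfg$target_noise_sd),
                  nrow = n)
  l2 <- intercepts + slope * log2(mirna_expr) + noise
  targets <- 2^l2
  rownames(targets) <- paste0(rownames(mirna_expr), "_target")
  colnames(targets) <- colnames(mirna_expr)
  list(targets = targets,
       coupling = data.frame(mirna = rownames(mirna_expr),
                             target = rownames(targets),
                             slope = slope, intercept = intercepts,
                             stringsAsFactors = FALSE))
}
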