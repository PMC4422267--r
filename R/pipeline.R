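#' Default pipeline configuration
#'
#' Effective parameter set for [run_pipeline()]; every value is recorded in
#' the run log and the JSON report. \code{simulate} holds overrides for
#' [simulation_config()] when no input files are given.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    counts = NULL, meta = NULL, weights = NULL,     # input paths (optional)
    candidates = NULL, stars = NULL,
    floor = 0.01, min_tpm = 10,
    tpm_high = 50, detection_floor = 0,
    completion_fraction = 0.95,
    cluster_k = 2L,
    correlation_method = "pearson",
    seed = 1L,
    simulate = list())
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort("unknown pipeline config field(s): ",
                         paste(bad, collapse = ", "),
                         class = "spikefill_config_error")
  modifyList(cfg, over)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order — simulate (or load) counts
#' and metadata, TPM-normalize, floor, abundance-filter, per-stage exact
#' tests and classification, cross-stage paired tests and summaries,
#' novel-candidate evaluation, logistic kinetics for both spikelet types, and
#' profile clustering with miRNA--target correlations — writing per-stage
#' TSVs, a JSON summary and a run log under \code{out_dir}. The report is a
#' pure function of (inputs, config, seed): rerunning with the same seed
#' reproduces the JSON byte-for-byte. Cross-parameter validation
#' (\code{min_tpm > floor}) happens before any stage runs, and the summary's
#' DE percentages are recomputed from the written DE table as an internal
#' consistency check.
#'
#' @param config list from [pipeline_config()], a plain list of overrides, or
#'   a path to a YAML file of overrides.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the stage results and the summary.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("spikefill_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_config(config)
  if (cfg$min_tpm <= cfg$floor) {
    abort("min_tpm (", cfg$min_tpm, ") must exceed floor (", cfg$floor, ")",
          class = "spikefill_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO",
                            paste0(...), "\n", file = log_path, append = TRUE)
  logf("spikefill ", as.character(utils::packageVersion("spikefill")),
       " seed=", cfg$seed)
  logf("parameters: floor=", cfg$floor, " min_tpm=", cfg$min_tpm,
       " tpm_high=", cfg$tpm_high, " cluster_k=", cfg$cluster_k)

  run_stage <- function(name, expr) {
    logf("stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "spikefill_stage_error")
    })
    logf("stage ", name, " done")
    res
  }

  # --- inputs: load or simulate ------------------------------------------
  sim <- NULL
  if (is.null(cfg$counts)) {
    sim <- run_stage("simulate", {
      scfg <- do.call(simulation_config,
                      modifyList(list(seed = cfg$seed), cfg$simulate))
      simulate_counts(scfg)
    })
    counts <- sim$counts; meta <- sim$meta
    write_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_results(meta, file.path(out_dir, "meta.tsv"))
  } else {
    counts <- run_stage("load_counts", read_count_matrix(cfg$counts))
    meta <- run_stage("load_meta", read_metadata(cfg$meta))
  }

  # --- normalization ------------------------------------------------------
  norm <- run_stage("normalize", {
    expr <- apply_floor(tpm_normalize(counts, meta), cfg$floor)
    filt <- abundance_filter(expr, threshold = cfg$min_tpm, floor = cfg$floor)
    write_matrix(expr, file.path(out_dir, "expression.tsv"))
    list(expr = expr, kept = filt$kept, dropped_ids = filt$dropped_ids)
  })

  # --- differential expression -------------------------------------------
  de <- run_stage("detest", {
    kept_ids <- rownames(norm$kept)
    recs <- stage_comparison(counts[kept_ids, , drop = FALSE], meta,
                             expr = norm$kept, floor = cfg$floor)
    write_results(recs, file.path(out_dir, "de.tsv"))
    recs
  })
  paired <- run_stage("paired_tests", {
    meta_s <- meta[order(meta$stage_daf), ]
    sup_libs <- meta_s$library_id[meta_s$condition == "superior"]
    inf_libs <- meta_s$library_id[meta_s$condition == "inferior"]
    l2 <- log2_profile_matrix(norm$kept)
    out <- do.call(rbind, lapply(rownames(l2), function(id) {
      cbind(entity_id = id, paired_ttest(l2[id, sup_libs], l2[id, inf_libs]))
    }))
    write_results(out, file.path(out_dir, "paired.tsv"))
    out
  })
  de_summary <- run_stage("summarize", summarize_de(de, paired))
  write_results(de_summary$per_stage, file.path(out_dir, "de_summary.tsv"))

  # --- novel candidates ---------------------------------------------------
  novel <- run_stage("novel", {
    if (!is.null(cfg$candidates)) {
      cand <- read_novel_candidates(cfg$candidates, cfg$stars)
      evaluate_all(cand$tpm, cand$star, tpm_high = cfg$tpm_high,
                   detection_floor = cfg$detection_floor)
    } else if (!is.null(sim)) {
      # treat the simulated star-flagged entities as the candidate pool
      pool <- sim$truth$star_entities
      if (length(pool)) {
        evaluate_all(norm$expr[pool, , drop = FALSE],
                     sim$star[pool, , drop = FALSE],
                     tpm_high = cfg$tpm_high,
                     detection_floor = cfg$detection_floor)
      } else NULL
    } else NULL
  })
  if (!is.null(novel)) write_results(novel, file.path(out_dir, "novel.tsv"))

  # --- kinetics -----------------------------------------------------------
  kin <- run_stage("kinetics", {
    wts <- if (!is.null(cfg$weights)) {
      read.delim(cfg$weights, stringsAsFactors = FALSE)
    } else if (!is.null(sim)) {
      scfg <- do.call(simulation_config,
                      modifyList(list(seed = cfg$seed), cfg$simulate))
      simulate_weights(scfg)
    } else NULL
    if (is.null(wts)) NULL else {
      fits <- lapply(split(wts, wts$condition), function(d) {
        fit_logistic(d$daf, d$weight)
      })
      summ <- do.call(rbind, lapply(names(fits), function(cond) {
        f <- fits[[cond]]
        cbind(condition = cond, K = f$K, a = f$a, b = f$b, rss = f$rss,
              kinetics_summary(f, cfg$completion_fraction))
      }))
      write_results(summ, file.path(out_dir, "kinetics.tsv"))
      list(fits = fits, summary = summ)
    }
  })

  # --- profiles -----------------------------------------------------------
  prof <- run_stage("profiles", {
    l2 <- log2_profile_matrix(norm$kept)
    cl <- if (nrow(l2) >= max(2L, cfg$cluster_k)) {
      cluster_profiles(l2, k = cfg$cluster_k)
    } else NULL
    if (!is.null(cl)) {
      write_results(data.frame(entity_id = names(cl$clusters),
                               cluster = unname(cl$clusters)),
                    file.path(out_dir, "clusters.tsv"))
    }
    cors <- NULL
    if (!is.null(sim)) {
      scfg <- do.call(simulation_config,
                      modifyList(list(seed = cfg$seed), cfg$simulate))
      tg <- simulate_targets(scfg, norm$kept)
      cors <- do.call(rbind, lapply(seq_len(nrow(norm$kept)), function(i) {
        cbind(mirna = rownames(norm$kept)[i],
              mirna_target_correlation(log2(norm$kept[i, ]),
                                       log2(tg$targets[i, ]),
                                       method = cfg$correlation_method))
      }))
      write_results(cors, file.path(out_dir, "correlations.tsv"))
    }
    list(clusters = cl, correlations = cors)
  })

  # --- report -------------------------------------------------------------
  summary <- run_stage("report", {
    # internal consistency: summary must be re-derivable from the written table
    reread <- read.delim(file.path(out_dir, "de.tsv"), stringsAsFactors = FALSE)
    again <- summarize_de(reread)$per_stage
    if (!isTRUE(all.equal(again$n_de, de_summary$per_stage$n_de)) ||
        !isTRUE(all.equal(again$pct_higher_superior,
                          de_summary$per_stage$pct_higher_superior))) {
      abort("internal consistency check failed: DE summary does not match its table")
    }
    s <- list(
      seed = cfg$seed,
      parameters = cfg[c("floor", "min_tpm", "tpm_high", "detection_floor",
                         "completion_fraction", "cluster_k",
                         "correlation_method")],
      n_entities = nrow(counts),
      n_kept = nrow(norm$kept),
      n_dropped = length(norm$dropped_ids),
      de_per_stage = de_summary$per_stage,
      de_overall = de_summary$overall,
      novel = if (!is.null(novel)) list(n_candidates = nrow(novel),
                                        n_accepted = sum(novel$accepted)) else NULL,
      kinetics = if (!is.null(kin)) kin$summary else NULL,
      mean_target_correlation = if (!is.null(prof$correlations))
        mean(prof$correlations$correlation, na.rm = TRUE) else NULL)
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    s
  })
  logf("pipeline complete")
  invisible(list(out_dir = out_dir, counts = counts, meta = meta,
                 normalization = norm, de = de, paired = paired,
                 de_summary = de_summary, novel = novel, kinetics = kin,
                 profiles = prof, summary = summary, sim = sim))
}
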