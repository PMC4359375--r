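#' Analyze a Poly-Ribo-Seq experiment held in memory
#'
#' The in-memory core of the pipeline: discovers features on the
#' transcriptome, computes per-fraction metrics, derives background
#' thresholds from the 3'-UTRs of transcribed canonical mRNAs in the
#' small-polysome fraction (falling back to [default_thresholds()] with a
#' warning when that set is empty), calls translation per fraction, combines
#' the calls by union, and tabulates the per-category report. Optionally
#' appends mean conservation and conserved flags when a conservation track is
#' supplied.
#'
#' @param txome a [transcriptome()].
#' @param fp named list of footprint alignment data.frames, one per fraction
#'   (names become `fraction_label`s; thresholds come from
#'   `"small_polysome"` if present, else the first element).
#' @param mrna mRNA-fragment alignments (total control).
#' @param conservation optional list with `blocks` and `intergenic_scores`
#'   (as from [simulate_conservation()] or read from a scored BED).
#' @param params an [orf_params()].
#' @param offsets P-site offset map.
#' @param percentile,coverage_floor,min_reads,alpha threshold settings
#'   (see [derive_thresholds()]).
#' @param n_samples null draws for [expression_significance()].
#' @param seed integer seed for the randomized expression background.
#' @return list: `features`, `metrics` (named list per fraction), `thresholds`,
#'   `calls` (named list), `combined`, `report`, and (when supplied)
#'   `conservation_scores` (`feature_id`, `mean_score`, `conserved`) plus
#'   `conservation_cutoff`.
#' @export
analyze_experiment <- function(txome, fp, mrna, conservation = NULL,
                               params = orf_params(),
                               offsets = default_psite_offsets(),
                               percentile = 90, coverage_floor = 0.57,
                               min_reads = 5L, alpha = 0.01,
                               n_samples = 1000L, seed = 1L) {
  if (is.null(names(fp)) || any(names(fp) == "")) {
    stop("analyze_experiment: fp must be a named list of fractions")
  }
  features <- discover_features(txome, params)
  expr_p <- if (sum(mrna$multiplicity) > 0) {
    expression_significance(features, mrna, txome, n_samples = n_samples,
                            seed = seed)
  } else NULL
  metrics <- list()
  for (fr in names(fp)) {
    metrics[[fr]] <- compute_feature_metrics(
      features, fp[[fr]], mrna, txome, offsets = offsets,
      fraction_label = fr, n_samples = n_samples, seed = seed, alpha = alpha,
      expression_p = expr_p)
  }

  bg_fraction <- if ("small_polysome" %in% names(fp)) "small_polysome" else names(fp)[1]
  bg <- background_utr3_metrics(metrics[[bg_fraction]], alpha = alpha)
  thresholds <- if (nrow(bg) > 0) {
    derive_thresholds(bg, percentile = percentile,
                      coverage_floor = coverage_floor,
                      min_reads = min_reads, alpha = alpha)
  } else {
    warning("analyze_experiment: no transcribed canonical 3'-UTR background; ",
            "using the default threshold set")
    default_thresholds()
  }

  calls <- lapply(metrics, call_translation, thresholds = thresholds)
  translated_sets <- lapply(calls, function(cl) cl$feature_id[cl$translated])
  combined <- combine_calls(translated_sets)
  report <- export_report(metrics, calls, alpha = alpha)

  res <- list(features = features, metrics = metrics, thresholds = thresholds,
              calls = calls, combined = combined, report = report)
  if (!is.null(conservation)) {
    cutoff <- conservation_threshold(conservation$intergenic_scores, percentile)
    scores <- vapply(seq_len(nrow(features)), function(i) {
      mean_conservation(features[i, ], conservation$blocks)
    }, numeric(1))
    res$conservation_scores <- data.frame(
      feature_id = features$feature_id, mean_score = scores,
      conserved = flag_conserved(scores, cutoff))
    res$conservation_cutoff <- cutoff
  }
  res
}

#' Background set for threshold derivation
#'
#' Restricts a metrics table to the 3'-UTRs of canonical (> 100 aa) coding
#' transcripts with significant mRNA expression ("transcribed":
#' `expression_p < alpha` and `mrna_rpkm > 0`). Because the empirical
#' expression p-values are density ranks over the transcript space, the
#' strict gate can leave only a handful of UTRs, and a percentile over so few
#' points is not a meaningful cut-off; when fewer than `min_n` UTRs pass, the
#' gate is relaxed to mRNA presence (`mrna_rpkm > 0`) with a warning.
#'
#' @param metrics output of [compute_feature_metrics()] for one fraction.
#' @param alpha expression gate.
#' @param min_n smallest background size accepted under the strict gate.
#' @return subset of `metrics` rows.
#' @export
background_utr3_metrics <- function(metrics, alpha = 0.01, min_n = 20L) {
  canon_tx <- unique(metrics$transcript_id[metrics$category == "canonical_cds"])
  base <- metrics$category == "utr3_background" &
    metrics$transcript_id %in% canon_tx & metrics$mrna_rpkm > 0
  strict <- base & metrics$expression_p < alpha
  if (sum(strict) >= min_n) return(metrics[strict, , drop = FALSE])
  if (sum(base) > 0 && sum(base) > sum(strict)) {
    warning("background_utr3_metrics: only ", sum(strict),
            " 3'-UTRs pass the expression-significance gate; ",
            "relaxing to mRNA presence (n = ", sum(base), ")")
  }
  metrics[base, , drop = FALSE]
}

#' Per-category summary report
#'
#' For each feature category and fraction: transcribed features (mRNA
#' expression significant), how many of those are called translated vs
#' untranslated, and the median TE over defined TEs. Undefined TEs are
#' excluded from medians; a category with no defined TE reports `NA`.
#' `translated + untranslated == transcribed` by construction.
#'
#' @param metrics named list of per-fraction metrics tables.
#' @param calls named list of per-fraction call tables (same fractions).
#' @param alpha expression gate defining "transcribed".
#' @return data.frame (`category`, `fraction_label`, `n_features`,
#'   `n_transcribed`, `n_translated`, `n_untranslated`, `median_te`).
#' @export
export_report <- function(metrics, calls, alpha = 0.01) {
  out <- list()
  for (fr in names(metrics)) {
    m <- metrics[[fr]]
    cl <- calls[[fr]]
    translated <- cl$translated[match(m$feature_id, cl$feature_id)]
    transcribed <- m$expression_p < alpha & m$mrna_rpkm > 0
    for (cat in unique(m$category)) {
      sel <- m$category == cat
      n_tr <- sum(transcribed[sel])
      n_called <- sum(transcribed[sel] & translated[sel])
      out[[length(out) + 1L]] <- data.frame(
        category = cat, fraction_label = fr,
        n_features = sum(sel),
        n_transcribed = n_tr,
        n_translated = n_called,
        n_untranslated = n_tr - n_called,
        median_te = median_defined(m$te[sel])
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' File-based configuration for [run_pipeline()]: input paths, parameters and
#' the output directory. `thresholds = "derive"` derives cut-offs from the
#' 3'-UTR background; a `threshold_set` uses fixed cut-offs instead.
#'
#' @param fasta,structure transcriptome inputs (see [load_transcripts()]).
#' @param fp named character vector of footprint BED paths per fraction.
#' @param mrna mRNA-fragment BED path.
#' @param conservation optional scored-BED path of conservation blocks.
#' @param intergenic_scores optional numeric vector of intergenic mean scores
#'   (required for conservation flags when `conservation` is given).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param thresholds `"derive"` or a `threshold_set`.
#' @param params,offsets,percentile,coverage_floor,min_reads,alpha,n_samples
#'   as in [analyze_experiment()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, structure, fp, mrna, out_dir,
                            conservation = NULL, intergenic_scores = NULL,
                            seed = 1L, thresholds = "derive",
                            params = orf_params(),
                            offsets = default_psite_offsets(),
                            percentile = 90, coverage_floor = 0.57,
                            min_reads = 5L, alpha = 0.01, n_samples = 1000L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the file-based pipeline
#'
#' Reads the configured inputs, runs [analyze_experiment()], and writes the
#' report bundle into `out_dir`: `metrics_<fraction>.tsv`,
#' `calls_<fraction>.tsv`, `combined_calls.tsv`, `report.tsv`,
#' `metagene_start.tsv` / `metagene_stop.tsv` (small-polysome fraction),
#' `conservation_scores.tsv` (when configured), and `run_log.txt` recording
#' the package version, seed and threshold values. Existing output files
#' cause an error rather than a silent overwrite unless `overwrite = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param overwrite allow replacing existing outputs.
#' @return invisibly, the [analyze_experiment()] result list.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  txome <- load_transcripts(config$fasta, config$structure)
  fp <- lapply(config$fp, read_alignments_bed)
  names(fp) <- names(config$fp)
  mrna <- read_alignments_bed(config$mrna)
  conservation <- NULL
  if (!is.null(config$conservation)) {
    conservation <- list(blocks = read_conservation_bed(config$conservation),
                         intergenic_scores = config$intergenic_scores)
  }
  res <- analyze_experiment(
    txome, fp, mrna, conservation = conservation, params = config$params,
    offsets = config$offsets, percentile = config$percentile,
    coverage_floor = config$coverage_floor, min_reads = config$min_reads,
    alpha = config$alpha, n_samples = config$n_samples, seed = config$seed)
  if (!identical(config$thresholds, "derive")) {
    res$thresholds <- config$thresholds
    res$calls <- lapply(res$metrics, call_translation, thresholds = res$thresholds)
    res$combined <- combine_calls(lapply(res$calls,
                                         function(cl) cl$feature_id[cl$translated]))
    res$report <- export_report(res$metrics, res$calls, alpha = config$alpha)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_file <- function(name) {
    path <- file.path(config$out_dir, name)
    if (file.exists(path) && !overwrite) {
      stop("run_pipeline: output exists, not overwriting: ", path)
    }
    path
  }
  hdr <- sprintf("# polyribo %s | seed %d | rpkm_cutoff %.6g | coverage_cutoff %.6g | min_reads %d",
                 as.character(utils::packageVersion("polyribo")), config$seed,
                 res$thresholds$rpkm_cutoff, res$thresholds$coverage_cutoff,
                 res$thresholds$min_reads)
  write_tsv_hdr <- function(df, name) {
    path <- out_file(name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (fr in names(res$metrics)) {
    write_tsv_hdr(res$metrics[[fr]], sprintf("metrics_%s.tsv", fr))
    write_tsv_hdr(res$calls[[fr]], sprintf("calls_%s.tsv", fr))
  }
  write_tsv_hdr(res$combined, "combined_calls.tsv")
  write_tsv_hdr(res$report, "report.tsv")
  small <- if ("small_polysome" %in% names(fp)) fp$small_polysome else fp[[1]]
  write_tsv_hdr(metagene_composite(txome, small, "start"), "metagene_start.tsv")
  write_tsv_hdr(metagene_composite(txome, small, "stop"), "metagene_stop.tsv")
  if (!is.null(res$conservation_scores)) {
    write_tsv_hdr(res$conservation_scores, "conservation_scores.tsv")
  }
  log_path <- out_file("run_log.txt")
  writeLines(c(
    sprintf("%s polyribo %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            as.character(utils::packageVersion("polyribo"))),
    sprintf("seed: %d", config$seed),
    sprintf("fractions: %s", paste(names(fp), collapse = ", ")),
    sprintf("thresholds: rpkm >= %.6g, coverage >= %.6g, min_reads >= %d",
            res$thresholds$rpkm_cutoff, res$thresholds$coverage_cutoff,
            res$thresholds$min_reads)
  ), log_path)
  invisible(res)
}
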