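#' Reads per kilobase per million mapped reads
#'
#' `count / (feature_length/1000) / (total_mapped/1e6)`. The library-size
#' denominator is the total of retained transcript-aligned reads
#' (multiplicity-weighted) for the experiment at hand.
#'
#' @param count reads anchored in the feature.
#' @param feature_length feature length in nt (> 0).
#' @param total_mapped library size in reads (> 0).
#' @return density (vectorized).
#' @export
rpkm <- function(count, feature_length, total_mapped) {
  if (any(feature_length <= 0)) stop("rpkm: feature_length must be > 0")
  if (any(total_mapped <= 0)) stop("rpkm: total_mapped must be > 0")
  count / (feature_length / 1000) / (total_mapped / 1e6)
}

#' Empirical mRNA-expression significance against a randomized background
#'
#' For each feature, draws `n_samples` length-matched intervals uniformly over
#' the concatenated transcript space and compares their mRNA read counts with
#' the observed count; `p = (1 + #{null >= observed}) / (n_samples + 1)`.
#' mRNA fragments are anchored at their midpoints.
#'
#' @param features feature table (`transcript_id`, `start`, `end`).
#' @param mrna mRNA-fragment alignment data.frame.
#' @param txome a [transcriptome()].
#' @param n_samples number of null intervals per feature (>= 100).
#' @param seed integer seed for the null placements.
#' @return numeric vector of empirical p-values, one per feature row.
#' @export
expression_significance <- function(features, mrna, txome, n_samples = 1000L,
                                    seed = NULL) {
  if (n_samples < 100L) stop("expression_significance: n_samples must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  tx_len <- txome$info$length
  names(tx_len) <- txome$info$transcript_id
  offset <- c(0, cumsum(as.numeric(tx_len)))[seq_along(tx_len)]
  names(offset) <- names(tx_len)
  total_len <- sum(as.numeric(tx_len))

  anchors <- offset[mrna$transcript_id] + anchor_positions(mrna, "midpoint")
  o <- order(anchors)
  anchors <- anchors[o]
  cummult <- cumsum(mrna$multiplicity[o])
  count_in <- function(lo, hi) { # counts with anchor in [lo, hi)
    i_hi <- findInterval(hi - 1e-9, anchors)
    i_lo <- findInterval(lo - 1e-9, anchors)
    hi_c <- ifelse(i_hi > 0, cummult[pmax(i_hi, 1L)], 0)
    hi_c[i_hi == 0] <- 0
    lo_c <- ifelse(i_lo > 0, cummult[pmax(i_lo, 1L)], 0)
    lo_c[i_lo == 0] <- 0
    hi_c - lo_c
  }

  nf <- nrow(features)
  flen <- features$end - features$start
  if (any(flen > total_len)) {
    stop("expression_significance: feature '",
         features$feature_id[which(flen > total_len)[1]],
         "' longer than the transcript space")
  }
  glo <- offset[features$transcript_id] + features$start
  obs <- count_in(glo, glo + flen)
  # all null placements drawn and counted in one pass (feature-major order)
  flen_rep <- rep(flen, each = n_samples)
  starts <- floor(stats::runif(nf * n_samples, 0, total_len - flen_rep + 1))
  nulls <- count_in(starts, starts + flen_rep)
  exceed <- nulls >= rep(obs, each = n_samples)
  (1 + colSums(matrix(exceed, nrow = n_samples))) / (n_samples + 1)
}

#' Translational efficiency
#'
#' TE = footprint RPKM / mRNA RPKM, computed only for features whose mRNA
#' expression is significant against the randomized background
#' (`expression_p < alpha`) and non-zero; otherwise `NA` (undefined, a value
#' and not an error).
#'
#' @param fp_rpkm,mrna_rpkm footprint and mRNA densities (vectorized).
#' @param expression_p empirical expression p-values.
#' @param alpha significance gate (default 0.01).
#' @return TE ratios with `NA` where undefined.
#' @export
translational_efficiency <- function(fp_rpkm, mrna_rpkm, expression_p,
                                     alpha = 0.01) {
  if (any(fp_rpkm < 0, na.rm = TRUE) || any(mrna_rpkm < 0, na.rm = TRUE)) {
    stop("translational_efficiency: densities must be >= 0")
  }
  ifelse(expression_p < alpha & mrna_rpkm > 0, fp_rpkm / mrna_rpkm, NA_real_)
}

#' Paper-default translation thresholds
#'
#' The published cut-offs for calling translation when no background set is
#' supplied: 11.8 RPKM, 0.57 coverage, at least 5 reads in a single
#' experiment.
#'
#' @return `threshold_set` list.
#' @export
default_thresholds <- function() {
  structure(list(rpkm_cutoff = 11.8, coverage_cutoff = 0.57,
                 coverage_percentile_raw = NA_real_, min_reads = 5L,
                 background_percentile = 90, alpha = 0.01,
                 n_background = NA_integer_),
            class = "threshold_set")
}

#' Derive translation-calling thresholds from 3'-UTR background
#'
#' Takes per-feature metrics of the 3'-UTRs of transcribed canonical
#' (>100 aa) mRNAs — the background signal of lowly translated non-coding
#' sequence — and sets the RPKM and coverage cut-offs at their 90th
#' percentiles. The coverage cut-off is floored at 0.57: a dwarf smORF under
#' 20 aa holding a single ribosome can still appear 0.56 covered
#' (32 nt / 57 nt), so percentile values below the floor are raised to it.
#' The minimum-read rule (>= 5 reads in a single experiment) guards against
#' RPKM inflation from very few reads on short features.
#'
#' @param utr3_metrics data.frame with columns `fp_rpkm` and `coverage`
#'   restricted to the background feature set.
#' @param percentile background percentile (default 90).
#' @param coverage_floor floor for the coverage cut-off (default 0.57).
#' @param min_reads minimum read count (default 5).
#' @param alpha expression-significance level carried into calling (0.01).
#' @return `threshold_set` list with elements `rpkm_cutoff`,
#'   `coverage_cutoff`, `coverage_percentile_raw`, `min_reads`,
#'   `background_percentile`, `alpha`, `n_background`.
#' @export
derive_thresholds <- function(utr3_metrics, percentile = 90,
                              coverage_floor = 0.57, min_reads = 5L,
                              alpha = 0.01) {
  if (is.null(utr3_metrics) || nrow(utr3_metrics) == 0L) {
    stop("derive_thresholds: empty background set; ",
         "use default_thresholds() (11.8 RPKM, 0.57 coverage, 5 reads) instead")
  }
  p <- percentile / 100
  cov_raw <- quantile_linear(utr3_metrics$coverage, p)
  structure(list(
    rpkm_cutoff = quantile_linear(utr3_metrics$fp_rpkm, p),
    coverage_cutoff = max(cov_raw, coverage_floor),
    coverage_percentile_raw = cov_raw,
    min_reads = as.integer(min_reads),
    background_percentile = percentile,
    alpha = alpha,
    n_background = nrow(utr3_metrics)
  ), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: rpkm >= %.3g, coverage >= %.3g, reads >= %d (background n = %s, pctl %.0f)\n",
              x$rpkm_cutoff, x$coverage_cutoff, x$min_reads,
              ifelse(is.na(x$n_background), "-", x$n_background),
              x$background_percentile))
  invisible(x)
}

#' Call translation of features
#'
#' A feature is translated iff all three filters pass (inclusive "at least"
#' boundaries): footprint RPKM >= rpkm_cutoff, coverage >= coverage_cutoff,
#' and read count >= min_reads.
#'
#' @param metrics data.frame with `feature_id`, `fp_rpkm`, `coverage`,
#'   `fp_count`.
#' @param thresholds a `threshold_set` from [derive_thresholds()] or
#'   [default_thresholds()].
#' @return data.frame (`feature_id`, `pass_rpkm`, `pass_coverage`,
#'   `pass_min_reads`, `translated`).
#' @export
call_translation <- function(metrics, thresholds) {
  pr <- metrics$fp_rpkm >= thresholds$rpkm_cutoff
  pc <- metrics$coverage >= thresholds$coverage_cutoff
  pm <- metrics$fp_count >= thresholds$min_reads
  data.frame(feature_id = metrics$feature_id,
             pass_rpkm = pr, pass_coverage = pc, pass_min_reads = pm,
             translated = pr & pc & pm)
}

#' Combine translated-ID sets across experiments (union with provenance)
#'
#' @param call_sets named list of character vectors of translated feature ids.
#' @return data.frame (`feature_id`, `experiments` comma-joined,
#'   `n_experiments`), one row per id in the union.
#' @export
combine_calls <- function(call_sets) {
  if (length(call_sets) == 0L) stop("combine_calls: need at least one set")
  if (is.null(names(call_sets)) || any(names(call_sets) == "")) {
    names(call_sets) <- sprintf("experiment%d", seq_along(call_sets))
  }
  ids <- sort(unique(unlist(call_sets, use.names = FALSE)))
  membership <- vapply(ids, function(id) {
    paste(names(call_sets)[vapply(call_sets, function(s) id %in% s, logical(1))],
          collapse = ",")
  }, character(1))
  data.frame(feature_id = ids, experiments = unname(membership),
             n_experiments = lengths(strsplit(unname(membership), ",")))
}

#' Squared correlation of footprint densities between replicates
#'
#' @param metrics_a,metrics_b data.frames with `feature_id` and `fp_rpkm`.
#' @return R^2 (square of the sample correlation over shared features).
#' @export
replicate_correlation <- function(metrics_a, metrics_b) {
  shared <- intersect(metrics_a$feature_id, metrics_b$feature_id)
  a <- metrics_a$fp_rpkm[match(shared, metrics_a$feature_id)]
  b <- metrics_b$fp_rpkm[match(shared, metrics_b$feature_id)]
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("replicate_correlation: fewer than 3 shared features")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("replicate_correlation: zero variance in a replicate")
  }
  stats::cor(a, b)^2
}

#' Per-feature translation metrics for one footprint library
#'
#' Computes, for every feature, the footprint count (P-site anchored),
#' footprint RPKM, per-base coverage (full read extents, lengths 28-34),
#' mRNA count/RPKM (midpoint anchored), empirical expression p-value and TE.
#' Counting internals are vectorized (per-transcript coverage runs and
#' cumulative anchor sums) but agree exactly with [coverage_fraction()] and
#' [feature_read_count()] applied feature by feature.
#'
#' With an empty footprint library all counts, RPKMs and coverages are zero
#' (with a warning) rather than an error, so background-only experiments can
#' still be tabulated.
#'
#' @param features feature table from [discover_features()].
#' @param fp footprint alignments (any lengths; filtered to
#'   `fp_length_range` internally).
#' @param mrna mRNA-fragment alignments.
#' @param txome a [transcriptome()].
#' @param offsets P-site offset map for anchoring footprint counts.
#' @param fraction_label label recorded in the output (`small_polysome`,
#'   `large_polysome` or `total`).
#' @param fp_length_range retained footprint lengths (default 28-34 nt).
#' @param n_samples,seed passed to [expression_significance()].
#' @param alpha TE expression gate.
#' @param expression_p optional precomputed expression p-values (one per
#'   feature row), e.g. shared across fractions that use the same mRNA
#'   control; computed internally when `NULL`.
#' @return data.frame: feature columns plus `fraction_label`, `fp_count`,
#'   `fp_rpkm`, `coverage`, `mrna_count`, `mrna_rpkm`, `expression_p`, `te`.
#' @export
compute_feature_metrics <- function(features, fp, mrna, txome,
                                    offsets = default_psite_offsets(),
                                    fraction_label = "small_polysome",
                                    fp_length_range = c(28L, 34L),
                                    n_samples = 1000L, seed = NULL,
                                    alpha = 0.01, expression_p = NULL) {
  fp <- filter_by_length(fp, fp_length_range[1], fp_length_range[2])
  total_fp <- sum(fp$multiplicity)
  total_mrna <- sum(mrna$multiplicity)
  flen <- features$end - features$start

  if (total_fp == 0) {
    warning("compute_feature_metrics: empty footprint library; ",
            "all footprint metrics set to zero")
    fp_count <- rep(0L, nrow(features))
    fp_rpkm_v <- rep(0, nrow(features))
    cov <- rep(0, nrow(features))
  } else {
    fp_count <- count_anchored(features, fp, "psite", offsets, txome)
    fp_rpkm_v <- rpkm(fp_count, flen, total_fp)
    cov <- coverage_by_transcript(features, fp, txome)
  }
  if (total_mrna == 0) {
    mrna_count <- rep(0L, nrow(features))
    mrna_rpkm_v <- rep(0, nrow(features))
    expr_p <- rep(1, nrow(features))
  } else {
    mrna_count <- count_anchored(features, mrna, "midpoint", offsets, txome)
    mrna_rpkm_v <- rpkm(mrna_count, flen, total_mrna)
    expr_p <- if (!is.null(expression_p)) expression_p else
      expression_significance(features, mrna, txome,
                              n_samples = n_samples, seed = seed)
  }
  te <- translational_efficiency(fp_rpkm_v, mrna_rpkm_v, expr_p, alpha)
  cbind(features,
        data.frame(fraction_label = fraction_label, fp_count = fp_count,
                   fp_rpkm = fp_rpkm_v, coverage = cov,
                   mrna_count = mrna_count, mrna_rpkm = mrna_rpkm_v,
                   expression_p = expr_p, te = te))
}

# vectorized anchored counting over all features at once, via concatenated
# (global) transcript coordinates and cumulative multiplicity sums
count_anchored <- function(features, aln, mode, offsets, txome) {
  if (nrow(aln) == 0L) return(rep(0L, nrow(features)))
  tx_len <- txome$info$length
  goffset <- c(0, cumsum(as.numeric(tx_len)))[seq_along(tx_len)]
  names(goffset) <- txome$info$transcript_id
  pos <- goffset[aln$transcript_id] + anchor_positions(aln, mode, offsets)
  o <- order(pos)
  pos <- pos[o]
  cum <- cumsum(aln$multiplicity[o])
  glo <- goffset[features$transcript_id] + features$start
  ghi <- goffset[features$transcript_id] + features$end
  ih <- findInterval(ghi - 0.5, pos) # anchors strictly below the feature end
  il <- findInterval(glo - 0.5, pos)
  hi_c <- ifelse(ih > 0, cum[pmax(ih, 1L)], 0)
  lo_c <- ifelse(il > 0, cum[pmax(il, 1L)], 0)
  as.integer(hi_c - lo_c)
}

# vectorized per-base coverage of all features, one IRanges pass per transcript
coverage_by_transcript <- function(features, aln, txome) {
  cov <- numeric(nrow(features))
  for (tx in unique(features$transcript_id)) {
    fsel <- which(features$transcript_id == tx)
    asel <- aln$transcript_id == tx
    if (!any(asel)) next
    txlen <- txome$info$length[match(tx, txome$info$transcript_id)]
    rle_cov <- IRanges::coverage(
      IRanges::IRanges(start = aln$start[asel] + 1L, width = aln$length[asel]),
      width = txlen
    )
    bin <- rle_cov
    S4Vectors::runValue(bin) <- as.integer(S4Vectors::runValue(bin) > 0L)
    v <- IRanges::Views(bin, start = features$start[fsel] + 1L,
                        end = features$end[fsel])
    cov[fsel] <- IRanges::viewSums(v) / (features$end[fsel] - features$start[fsel])
  }
  cov
}
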