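#' Mean conservation score of a feature from scored blocks
#'
#' Overlap-length-weighted mean of block scores over the feature's bases.
#' Bases covered by no block contribute score 0 (conservative); set
#' `uncovered = "exclude"` to average over covered bases only. Blocks must
#' not overlap one another.
#'
#' @param feature list/one-row data.frame with `transcript_id` (or `space_id`),
#'   `start`, `end` in the blocks' coordinate space.
#' @param blocks data.frame with `space_id`, `start`, `end`, `score`
#'   (0-based half-open; scores in \[0, 1\]).
#' @param uncovered `"zero"` (default) or `"exclude"`.
#' @return mean score in \[0, 1\] (`NA` if `uncovered = "exclude"` and no
#'   block overlaps the feature).
#' @export
mean_conservation <- function(feature, blocks, uncovered = c("zero", "exclude")) {
  uncovered <- match.arg(uncovered)
  space <- if (!is.null(feature$space_id)) feature$space_id else feature$transcript_id
  flen <- feature$end - feature$start
  if (flen <= 0) stop("mean_conservation: empty feature interval")
  b <- blocks[blocks$space_id == space, , drop = FALSE]
  if (nrow(b) > 1L) {
    o <- order(b$start)
    if (any(b$end[o][-nrow(b)] > b$start[o][-1L])) {
      stop("mean_conservation: overlapping conservation blocks in '", space, "'")
    }
  }
  if (any(b$score < 0 | b$score > 1)) {
    stop("mean_conservation: block scores must lie in [0, 1]")
  }
  ov <- pmin(b$end, feature$end) - pmax(b$start, feature$start)
  ov <- pmax(ov, 0)
  covered <- sum(ov)
  weighted <- sum(ov * b$score)
  if (uncovered == "zero") weighted / flen
  else if (covered > 0) weighted / covered
  else NA_real_
}

#' Conservation cut-off from intergenic feature scores
#'
#' Percentile (default 90th) of mean conservation scores of intergenic
#' features, under the same linear-interpolation quantile convention as the
#' translation thresholds; features at or above the cut-off are flagged
#' conserved.
#'
#' @param intergenic_scores numeric vector of intergenic mean scores.
#' @param percentile percentile (default 90).
#' @return scalar cut-off.
#' @export
conservation_threshold <- function(intergenic_scores, percentile = 90) {
  if (length(intergenic_scores) == 0L) {
    stop("conservation_threshold: empty score list")
  }
  quantile_linear(intergenic_scores, percentile / 100)
}

#' Flag features as conserved
#' @param scores per-feature mean conservation scores.
#' @param cutoff from [conservation_threshold()].
#' @return logical vector (`score >= cutoff`).
#' @export
flag_conserved <- function(scores, cutoff) scores >= cutoff

#' Read conservation blocks from a scored BED file
#' @param path scored BED (chrom = coordinate space, score in \[0, 1\]).
#' @return data.frame (`space_id`, `start`, `end`, `score`).
#' @export
read_conservation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(space_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = as.numeric(gr$score))
}

#' Write conservation blocks to a scored BED file
#' @param blocks data.frame (`space_id`, `start`, `end`, `score`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_conservation_bed <- function(blocks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = blocks$space_id,
    ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$end),
    strand = "*"
  )
  gr$name <- sprintf("block%d", seq_len(nrow(blocks)))
  gr$score <- blocks$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
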