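STOP_CODONS <- c("TAA", "TAG", "TGA")

#' ORF discovery parameters
#'
#' @param min_aa minimum peptide length (amino acids, start Met included,
#'   stop excluded). Default 11, i.e. "longer than 10 aa".
#' @param require_atg if `TRUE` (default) ORFs must start at AUG; if `FALSE`
#'   stop-to-stop open frames are reported instead.
#' @param report_mode `"longest_per_stop"` (default): one ORF per
#'   (frame, stop), anchored at the 5'-most qualifying start;
#'   `"all_starts"`: every qualifying start reported.
#' @return list of class `orf_params`.
#' @export
orf_params <- function(min_aa = 11L, require_atg = TRUE,
                       report_mode = c("longest_per_stop", "all_starts")) {
  report_mode <- match.arg(report_mode)
  min_aa <- as.integer(min_aa)
  if (min_aa < 1L) stop("orf_params: min_aa must be >= 1")
  structure(list(min_aa = min_aa, require_atg = require_atg,
                 report_mode = report_mode), class = "orf_params")
}

#' Find AUG-initiated open reading frames in a nucleotide sequence
#'
#' Scans all three frames for ATG codons followed by an in-frame stop
#' (TAA/TAG/TGA) with no earlier in-frame stop. Returned intervals are
#' 0-based half-open and include the stop codon; peptide length
#' `aa_length = width/3 - 1`. Codons containing `N` never match start or
#' stop.
#'
#' @param sequence nucleotide string over `A,C,G,T,N`.
#' @param params an [orf_params()].
#' @return data.frame with columns `start`, `end`, `aa_length`, sorted by
#'   `start` (ties by `end`); zero rows when nothing qualifies.
#' @export
find_orfs <- function(sequence, params = orf_params()) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("find_orfs: sequence must be over ACGTN")
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), aa_length = integer())
  if (n < 6L) return(empty)
  codons <- substring(sequence, 1:(n - 2L), 3:n) # codon starting at 1-based pos i
  stop_pos <- which(codons %in% STOP_CODONS)     # 1-based
  start_pos <- if (params$require_atg) which(codons == "ATG") else integer()

  out_start <- integer(); out_end <- integer()
  for (f in 0:2) {
    sp <- stop_pos[(stop_pos - 1L) %% 3L == f]
    if (length(sp) == 0L) next
    sp <- sort(sp)
    if (params$require_atg) {
      ap <- start_pos[(start_pos - 1L) %% 3L == f]
      if (length(ap) == 0L) next
      # first in-frame stop strictly after each start
      idx <- findInterval(ap, sp) + 1L
      ok <- idx <= length(sp)
      ap <- ap[ok]
      qp <- sp[idx[ok]]
    } else {
      # stop-to-stop frames: start right after the previous in-frame stop
      frame_first <- f + 1L
      ap <- c(frame_first, sp[-length(sp)] + 3L)
      qp <- sp
      ok <- qp > ap
      ap <- ap[ok]; qp <- qp[ok]
    }
    if (params$report_mode == "longest_per_stop" && length(ap)) {
      o <- order(qp, ap)
      ap <- ap[o]; qp <- qp[o]
      keep <- !duplicated(qp) # first start per stop is the 5'-most
      ap <- ap[keep]; qp <- qp[keep]
    }
    out_start <- c(out_start, ap - 1L)  # 0-based
    out_end <- c(out_end, qp + 2L)      # stop codon included
  }
  if (length(out_start) == 0L) return(empty)
  aa <- (out_end - out_start) %/% 3L - 1L
  keep <- aa >= params$min_aa
  res <- data.frame(start = out_start[keep], end = out_end[keep],
                    aa_length = aa[keep])
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify an annotated CDS as smORF or canonical
#'
#' smORFs encode at most 100 amino acids (CDS of at most 303 nt including the
#' stop codon); longer CDSs are canonical.
#'
#' @param txome a [transcriptome()].
#' @param transcript_id a coding transcript.
#' @return `"smorf_cds"` or `"canonical_cds"`.
#' @export
classify_annotated_cds <- function(txome, transcript_id) {
  i <- match(transcript_id, txome$info$transcript_id)
  if (is.na(i)) stop("unknown transcript '", transcript_id, "'")
  if (txome$info$biotype[i] != "coding") {
    stop("no annotated CDS: transcript '", transcript_id, "' is noncoding")
  }
  cds_len <- txome$info$cds_end[i] - txome$info$utr5_end[i]
  aa <- cds_len %/% 3L - 1L
  if (aa <= 100L) "smorf_cds" else "canonical_cds"
}

#' Discover upstream ORFs in a coding transcript's 5'-UTR
#'
#' uORFs must be fully contained in the 5'-UTR, stop codon included; ORFs
#' whose stop would lie in or beyond the CDS are not reported, which keeps
#' uORF metrics independent of CDS footprint signal.
#'
#' @param txome a [transcriptome()].
#' @param transcript_id a coding transcript.
#' @param params an [orf_params()].
#' @return data.frame of features (`feature_id`, `transcript_id`, `start`,
#'   `end`, `category = "uorf"`, `aa_length`); zero rows for noncoding or
#'   UTR-less transcripts.
#' @export
discover_uorfs <- function(txome, transcript_id, params = orf_params()) {
  reg <- tx_regions(txome, transcript_id)
  empty <- orf_feature_frame()
  if (is.null(reg$cds) || is.null(reg$utr5)) return(empty)
  utr5_seq <- substr(txome$sequence[[transcript_id]], 1L, reg$utr5[2])
  hits <- find_orfs(utr5_seq, params)
  if (nrow(hits) == 0L) return(empty)
  orf_feature_frame(
    feature_id = sprintf("%s_uORF%d", transcript_id, seq_len(nrow(hits))),
    transcript_id = transcript_id,
    start = hits$start, end = hits$end,
    category = "uorf", aa_length = hits$aa_length
  )
}

#' Discover ORFs in a noncoding transcript
#'
#' Reports qualifying AUG-initiated ORFs anywhere in the transcript, with
#' feature ids numbered ORF1, ORF2, ... in 5' to 3' order.
#'
#' @inheritParams discover_uorfs
#' @return data.frame of `ncorf` features as in [discover_uorfs()].
#' @export
discover_ncorfs <- function(txome, transcript_id, params = orf_params()) {
  i <- match(transcript_id, txome$info$transcript_id)
  if (is.na(i)) stop("unknown transcript '", transcript_id, "'")
  if (txome$info$biotype[i] != "noncoding") {
    stop("expected noncoding transcript, got coding '", transcript_id, "'")
  }
  hits <- find_orfs(txome$sequence[[transcript_id]], params)
  if (nrow(hits) == 0L) return(orf_feature_frame())
  orf_feature_frame(
    feature_id = sprintf("%s_ORF%d", transcript_id, seq_len(nrow(hits))),
    transcript_id = transcript_id,
    start = hits$start, end = hits$end,
    category = "ncorf", aa_length = hits$aa_length
  )
}

#' 5'-UTR intervals remaining after masking uORFs
#'
#' Subtracts the union of uORF intervals from the 5'-UTR, giving the
#' "modified transcript" regions on which UTR occupancy is measured
#' independently of putative uORF translation.
#'
#' @param txome a [transcriptome()].
#' @param transcript_id a coding transcript with a 5'-UTR.
#' @param uorfs data.frame of uORF features on this transcript (may be empty).
#' @return data.frame (`start`, `end`) of disjoint sorted intervals.
#' @export
mask_uorfs_from_utr5 <- function(txome, transcript_id, uorfs) {
  reg <- tx_regions(txome, transcript_id)
  if (is.null(reg$utr5)) stop("transcript '", transcript_id, "' has no 5'-UTR")
  utr5 <- IRanges::IRanges(start = reg$utr5[1] + 1L, end = reg$utr5[2])
  if (nrow(uorfs) > 0) {
    if (any(uorfs$start < reg$utr5[1] | uorfs$end > reg$utr5[2])) {
      stop("uORF outside the 5'-UTR of transcript '", transcript_id, "'")
    }
    ur <- IRanges::reduce(IRanges::IRanges(start = uorfs$start + 1L, end = uorfs$end))
    kept <- IRanges::setdiff(utr5, ur)
  } else {
    kept <- utr5
  }
  data.frame(start = IRanges::start(kept) - 1L, end = IRanges::end(kept))
}

orf_feature_frame <- function(feature_id = character(), transcript_id = character(),
                              start = integer(), end = integer(),
                              category = character(), aa_length = integer()) {
  data.frame(feature_id = feature_id,
             transcript_id = rep_len(as.character(transcript_id), length(feature_id)),
             start = as.integer(start), end = as.integer(end),
             category = rep_len(as.character(category), length(feature_id)),
             aa_length = as.integer(aa_length))
}

#' Enumerate all features of a transcriptome
#'
#' Builds the master feature table over which metrics and calls are computed:
#' annotated CDSs (classified smORF vs canonical), uORFs, ncORFs, masked
#' 5'-UTR intervals (5'-UTR minus uORFs) and 3'-UTR background features.
#'
#' @param txome a [transcriptome()].
#' @param params an [orf_params()] used for uORF/ncORF discovery.
#' @return data.frame with columns `feature_id`, `transcript_id`, `start`,
#'   `end`, `category`, `aa_length` (`NA` for non-ORF features).
#' @export
discover_features <- function(txome, params = orf_params()) {
  out <- list()
  for (i in seq_len(nrow(txome$info))) {
    id <- txome$info$transcript_id[i]
    if (txome$info$biotype[i] == "coding") {
      reg <- tx_regions(txome, id)
      cds_len <- reg$cds[2] - reg$cds[1]
      out[[length(out) + 1L]] <- orf_feature_frame(
        feature_id = paste0(id, "_CDS"), transcript_id = id,
        start = reg$cds[1], end = reg$cds[2],
        category = classify_annotated_cds(txome, id),
        aa_length = cds_len %/% 3L - 1L
      )
      uorfs <- discover_uorfs(txome, id, params)
      if (nrow(uorfs)) out[[length(out) + 1L]] <- uorfs
      if (!is.null(reg$utr5)) {
        masks <- mask_uorfs_from_utr5(txome, id, uorfs)
        if (nrow(masks)) {
          out[[length(out) + 1L]] <- orf_feature_frame(
            feature_id = sprintf("%s_utr5m%d", id, seq_len(nrow(masks))),
            transcript_id = id, start = masks$start, end = masks$end,
            category = "utr5_mask", aa_length = NA_integer_
          )
        }
      }
      if (!is.null(reg$utr3)) {
        out[[length(out) + 1L]] <- orf_feature_frame(
          feature_id = paste0(id, "_utr3"), transcript_id = id,
          start = reg$utr3[1], end = reg$utr3[2],
          category = "utr3_background", aa_length = NA_integer_
        )
      }
    } else {
      ncorfs <- discover_ncorfs(txome, id, params)
      if (nrow(ncorfs)) out[[length(out) + 1L]] <- ncorfs
    }
  }
  if (length(out) == 0L) return(orf_feature_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peptide sequence of an ORF feature
#'
#' @param txome a [transcriptome()].
#' @param feature one row of a feature table (ORF category, stop included).
#' @return character peptide (stop codon dropped).
#' @export
orf_peptide <- function(txome, feature) {
  s <- substr(txome$sequence[[feature$transcript_id]],
              feature$start + 1L, feature$end - 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

#' Write ORF features as BED6 (+ TSV with category and peptide)
#'
#' BED6 in transcript coordinates: chrom = transcript_id, name = feature_id,
#' score = aa_length, strand = "+".
#'
#' @param txome a [transcriptome()].
#' @param features feature table from [discover_features()] (ORF rows only
#'   are given peptides; non-ORF rows get `NA`).
#' @param bed_file,tsv_file output paths (either may be `NULL` to skip).
#' @return invisibly, the feature table with a `peptide` column.
#' @export
write_orf_features <- function(txome, features, bed_file = NULL, tsv_file = NULL) {
  is_orf <- features$category %in% c("canonical_cds", "smorf_cds", "uorf", "ncorf")
  peptide <- rep(NA_character_, nrow(features))
  for (i in which(is_orf)) peptide[i] <- orf_peptide(txome, features[i, ])
  if (!is.null(bed_file)) {
    gr <- GenomicRanges::GRanges(
      seqnames = features$transcript_id,
      ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
      strand = "+"
    )
    gr$name <- features$feature_id
    gr$score <- ifelse(is.na(features$aa_length), 0L, features$aa_length)
    rtracklayer::export(gr, bed_file, format = "BED")
  }
  out <- cbind(features, peptide = peptide)
  if (!is.null(tsv_file)) {
    utils::write.table(out, tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
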