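#' Footprint / fragment alignment tables
#'
#' Alignments are plain data.frames in transcript coordinates with columns
#' `transcript_id`, `start` (0-based position of the read 5' end), `length`
#' (nt) and `multiplicity` (collapsed-duplicate count, default 1). The BED6
#' representation used on disk maps chrom = transcript_id,
#' chromStart/chromEnd = read extent, score = multiplicity, strand = "+".
#'
#' @param transcript_id,start,length,multiplicity column vectors (recycled).
#' @return alignment data.frame.
#' @export
alignments <- function(transcript_id = character(), start = integer(),
                       length = integer(), multiplicity = 1L) {
  n <- max(length(transcript_id), length(start), length(length))
  df <- data.frame(transcript_id = rep_len(as.character(transcript_id), n),
                   start = rep_len(as.integer(start), n),
                   length = rep_len(as.integer(length), n),
                   multiplicity = rep_len(as.integer(multiplicity), n))
  if (n > 0 && (any(df$start < 0) || any(df$length < 1) || any(df$multiplicity < 1))) {
    stop("alignments: start must be >= 0, length and multiplicity >= 1")
  }
  df
}

#' Read alignments from BED6 in transcript coordinates
#' @param path BED file path.
#' @return alignment data.frame (see [alignments()]).
#' @export
read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  score <- gr$score
  if (is.null(score)) score <- rep(1L, length(gr))
  score[is.na(score)] <- 1L
  alignments(transcript_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             length = GenomicRanges::width(gr),
             multiplicity = as.integer(score))
}

#' Write alignments as BED6 in transcript coordinates
#' @param aln alignment data.frame.
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_alignments_bed <- function(aln, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = aln$transcript_id,
    ranges = IRanges::IRanges(start = aln$start + 1L, width = aln$length),
    strand = "+"
  )
  gr$name <- sprintf("read%d", seq_len(nrow(aln)))
  gr$score <- aln$multiplicity
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Filter alignments by read length
#'
#' Gel-purification window for ribosome footprints; defaults keep 28-34 nt.
#' Order and multiplicities are preserved.
#'
#' @param aln alignment data.frame.
#' @param min_len,max_len inclusive length bounds.
#' @return filtered alignment data.frame.
#' @export
filter_by_length <- function(aln, min_len = 28L, max_len = 34L) {
  if (min_len > max_len) stop("filter_by_length: min_len > max_len")
  aln[aln$length >= min_len & aln$length <= max_len, , drop = FALSE]
}

#' Default P-site offsets
#'
#' Length-dependent offsets from the read 5' end to the ribosomal P-site:
#' +12 for 28-29 nt, +13 for 30-31 nt, +14 for 32 nt. Reads with lengths
#' absent from the map are excluded from P-site based analyses.
#'
#' @return named integer vector (names = read lengths).
#' @export
default_psite_offsets <- function() {
  c(`28` = 12L, `29` = 12L, `30` = 13L, `31` = 13L, `32` = 14L)
}

#' Assign P-site positions to reads
#'
#' P-site = read 5' end + offset(length). Lengths missing from the offset
#' map yield `NA` (excluded, not an error).
#'
#' @param aln alignment data.frame.
#' @param offsets named integer vector as from [default_psite_offsets()].
#' @param transcript_lengths optional named vector of transcript lengths; when
#'   given, a computed P-site at or beyond the transcript end raises an error.
#' @return integer vector of P-site positions (`NA` = excluded).
#' @export
assign_psite <- function(aln, offsets = default_psite_offsets(),
                         transcript_lengths = NULL) {
  if (any(offsets < 0) || any(offsets >= as.integer(names(offsets)))) {
    stop("assign_psite: offsets must be non-negative and smaller than the read length")
  }
  off <- offsets[as.character(aln$length)]
  psite <- ifelse(is.na(off), NA_integer_, aln$start + as.integer(off))
  if (!is.null(transcript_lengths)) {
    lim <- transcript_lengths[aln$transcript_id]
    bad <- !is.na(psite) & psite >= lim
    if (any(bad)) {
      stop("assign_psite: P-site beyond transcript end for '",
           aln$transcript_id[bad][1], "'")
    }
  }
  as.integer(psite)
}

# anchor positions used for feature counting: P-site where the length is in
# the offset map, read midpoint otherwise (and always midpoint for mRNA
# fragments), so adjacent features never double-count a read
anchor_positions <- function(aln, mode = c("psite", "midpoint"),
                             offsets = default_psite_offsets()) {
  mode <- match.arg(mode)
  if (mode == "midpoint") return(aln$start + aln$length %/% 2L)
  off <- offsets[as.character(aln$length)]
  as.integer(ifelse(is.na(off), aln$start + aln$length %/% 2L,
                    aln$start + as.integer(off)))
}

#' Fraction of a feature covered by footprints
#'
#' Per-base covered fraction using full read extents (not P-sites): the
#' fraction of feature bases overlapped by at least one read; partially
#' overlapping reads contribute only their overlapping bases. This is the
#' convention under which a single internal 32-nt footprint covers a 57-nt
#' dwarf smORF at 32/57 = 0.56.
#'
#' @param feature list/one-row data.frame with `transcript_id`, `start`, `end`.
#' @param aln alignment data.frame.
#' @return fraction in \[0, 1\].
#' @export
coverage_fraction <- function(feature, aln) {
  flen <- feature$end - feature$start
  if (flen <= 0) stop("coverage_fraction: zero-length feature")
  sel <- aln$transcript_id == feature$transcript_id
  if (!any(sel)) return(0)
  reads <- IRanges::reduce(IRanges::IRanges(start = aln$start[sel] + 1L,
                                            width = aln$length[sel]))
  fint <- IRanges::IRanges(start = feature$start + 1L, end = feature$end)
  covered <- sum(IRanges::width(IRanges::intersect(reads, fint)))
  covered / flen
}

#' Count reads anchored inside a feature
#'
#' Sums multiplicities of reads whose anchor position (P-site for footprints
#' with mapped lengths, read midpoint otherwise) lies in `[start, end)`.
#'
#' @param feature list/one-row data.frame with `transcript_id`, `start`, `end`.
#' @param aln alignment data.frame.
#' @param mode `"psite"` (footprints) or `"midpoint"` (mRNA fragments).
#' @param offsets P-site offset map used in `"psite"` mode.
#' @return integer count.
#' @export
feature_read_count <- function(feature, aln, mode = c("psite", "midpoint"),
                               offsets = default_psite_offsets()) {
  mode <- match.arg(mode)
  sel <- aln$transcript_id == feature$transcript_id
  if (!any(sel)) return(0L)
  a <- aln[sel, , drop = FALSE]
  pos <- anchor_positions(a, mode, offsets)
  as.integer(sum(a$multiplicity[pos >= feature$start & pos < feature$end]))
}

#' Metagene composite profile around start or stop codons
#'
#' Sums read 5'-end counts across coding transcripts at offsets relative to
#' the first base of the start codon (`anchor = "start"`) or of the stop
#' codon (`anchor = "stop"`). Offsets falling outside a transcript contribute
#' nothing. Window defaults: (-50, +100) around starts, (-100, +50) around
#' stops.
#'
#' @param txome a [transcriptome()].
#' @param aln alignment data.frame.
#' @param anchor `"start"` or `"stop"`.
#' @param window integer `c(min_offset, max_offset)` or `NULL` for defaults.
#' @return data.frame (`offset`, `count`).
#' @export
metagene_composite <- function(txome, aln, anchor = c("start", "stop"),
                               window = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window)) {
    window <- if (anchor == "start") c(-50L, 100L) else c(-100L, 50L)
  }
  coding <- txome$info[txome$info$biotype == "coding", ]
  if (nrow(coding) == 0L) stop("metagene_composite: no coding transcripts")
  anchors <- if (anchor == "start") coding$utr5_end else coding$cds_end - 3L
  names(anchors) <- coding$transcript_id
  offsets <- seq.int(window[1], window[2])
  counts <- integer(length(offsets))
  sel <- aln$transcript_id %in% coding$transcript_id
  a <- aln[sel, , drop = FALSE]
  if (nrow(a)) {
    rel <- a$start - anchors[a$transcript_id]
    inwin <- rel >= window[1] & rel <= window[2]
    if (any(inwin)) {
      tab <- tapply(a$multiplicity[inwin], rel[inwin], sum)
      counts[match(as.integer(names(tab)), offsets)] <- as.integer(tab)
    }
  }
  data.frame(offset = offsets, count = counts)
}

#' Triplet-frame distribution of P-sites in an ORF
#'
#' Frame of each P-site is `(psite - orf_start) mod 3`; frame 0 marks codon
#' starts. Only reads whose length is in the offset map and whose P-site lies
#' inside the ORF are counted. With zero included reads the result is an
#' undefined-result marker (total 0, `NA` fractions), not an error.
#'
#' @param orf list/one-row data.frame with `transcript_id`, `start`, `end`.
#' @param aln alignment data.frame.
#' @param offsets P-site offset map.
#' @return list of class `frame_stats`: `counts` (length 3), `fractions`,
#'   `total`.
#' @export
frame_distribution <- function(orf, aln, offsets = default_psite_offsets()) {
  counts <- frame_counts(orf, aln, offsets)
  total <- sum(counts)
  fr <- if (total > 0) counts / total else rep(NA_real_, 3)
  structure(list(counts = counts, fractions = fr, total = total),
            class = "frame_stats")
}

# raw per-frame multiplicity counts, shared by frame_distribution and the
# pooled variant
frame_counts <- function(orf, aln, offsets = default_psite_offsets()) {
  sel <- aln$transcript_id == orf$transcript_id
  counts <- c(0, 0, 0)
  if (any(sel)) {
    a <- aln[sel, , drop = FALSE]
    ps <- assign_psite(a, offsets)
    keep <- !is.na(ps) & ps >= orf$start & ps < orf$end
    if (any(keep)) {
      fr <- (ps[keep] - orf$start) %% 3L
      for (f in 0:2) counts[f + 1L] <- sum(a$multiplicity[keep][fr == f])
    }
  }
  counts
}

#' Pooled frame distribution over many features
#'
#' Sums per-frame P-site counts across features (each feature's frame taken
#' relative to its own start) and returns one `frame_stats`; used e.g. to
#' check the absence of triplet phasing over pooled UTR background.
#'
#' @param features feature table rows.
#' @param aln alignment data.frame.
#' @param offsets P-site offset map.
#' @return a `frame_stats` list as in [frame_distribution()].
#' @export
pooled_frame_distribution <- function(features, aln,
                                      offsets = default_psite_offsets()) {
  counts <- c(0, 0, 0)
  for (i in seq_len(nrow(features))) {
    counts <- counts + frame_counts(features[i, ], aln, offsets)
  }
  total <- sum(counts)
  fr <- if (total > 0) counts / total else rep(NA_real_, 3)
  structure(list(counts = counts, fractions = fr, total = total),
            class = "frame_stats")
}

#' @export
print.frame_stats <- function(x, ...) {
  cat("frame_stats: total", x$total, "P-sites; fractions",
      paste(sprintf("%.3f", x$fractions), collapse = "/"), "\n")
  invisible(x)
}
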