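#' Transcriptome container
#'
#' A `transcriptome` couples sense-strand transcript sequences with a
#' structure table giving, for each transcript, its gene, biotype and the
#' 5'UTR/CDS/3'UTR partition in 0-based half-open transcript coordinates:
#' `utr5 = [0, utr5_end)`, `cds = [utr5_end, cds_end)`,
#' `utr3 = [cds_end, length)`. Noncoding transcripts carry `NA` boundaries.
#' All downstream coordinates in the package live in this transcript space;
#' strand handling ends at ingestion.
#'
#' @param sequence named character vector (or `Biostrings::DNAStringSet`) of
#'   transcript sequences over `A,C,G,T,N`.
#' @param info data.frame with columns `transcript_id`, `gene_id`, `biotype`
#'   (`"coding"` or `"noncoding"`), `utr5_end`, `cds_end` (integers; `NA` for
#'   noncoding transcripts).
#' @return object of class `transcriptome`: a list with elements `sequence`
#'   (named character) and `info` (validated structure table with a `length`
#'   column added).
#' @export
transcriptome <- function(sequence, info) {
  if (methods::is(sequence, "DNAStringSet")) sequence <- as.character(sequence)
  if (is.null(names(sequence)) || anyDuplicated(names(sequence))) {
    stop("transcriptome: sequences must be uniquely named by transcript_id")
  }
  required <- c("transcript_id", "gene_id", "biotype", "utr5_end", "cds_end")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols)) {
    stop("transcriptome: structure table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  info <- info[, required]
  info$transcript_id <- as.character(info$transcript_id)
  info$gene_id <- as.character(info$gene_id)
  info$biotype <- as.character(info$biotype)
  info$utr5_end <- as.integer(info$utr5_end)
  info$cds_end <- as.integer(info$cds_end)

  absent <- setdiff(info$transcript_id, names(sequence))
  if (length(absent)) {
    stop("transcriptome: missing sequence for transcript '", absent[[1]], "'")
  }
  sequence <- toupper(sequence[info$transcript_id])
  bad_alpha <- grepl("[^ACGTN]", sequence)
  if (any(bad_alpha)) {
    stop("transcriptome: non-ACGTN characters in sequence of '",
         info$transcript_id[bad_alpha][[1]], "'")
  }
  info$length <- unname(nchar(sequence))

  for (i in seq_len(nrow(info))) {
    id <- info$transcript_id[i]
    bt <- info$biotype[i]
    if (!bt %in% c("coding", "noncoding")) {
      stop("transcriptome: unknown biotype '", bt, "' for transcript '", id, "'")
    }
    if (bt == "noncoding") {
      if (!is.na(info$utr5_end[i]) || !is.na(info$cds_end[i])) {
        stop("transcriptome: noncoding transcript '", id,
             "' must have empty CDS boundaries")
      }
      next
    }
    u5 <- info$utr5_end[i]; ce <- info$cds_end[i]; len <- info$length[i]
    if (is.na(u5) || is.na(ce)) {
      stop("transcriptome: coding transcript '", id, "' lacks CDS boundaries")
    }
    if (u5 < 0 || u5 > ce || ce > len) {
      stop("transcriptome: contradictory boundaries for transcript '", id, "'")
    }
    cds_len <- ce - u5
    if (cds_len <= 0 || cds_len %% 3L != 0L) {
      stop("transcriptome: CDS length not multiple of 3 for transcript '", id, "'")
    }
  }
  structure(list(sequence = sequence, info = info), class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  n_cod <- sum(x$info$biotype == "coding")
  cat("transcriptome:", nrow(x$info), "transcripts (", n_cod, "coding,",
      nrow(x$info) - n_cod, "noncoding )\n")
  invisible(x)
}

#' Load a transcriptome from FASTA plus a structure table
#'
#' @param fasta_file path to a transcript FASTA.
#' @param structure_file path to a tab-separated structure table with header
#'   `transcript_id gene_id biotype utr5_end cds_end`; noncoding rows leave
#'   both boundary fields empty.
#' @return a [transcriptome()].
#' @export
load_transcripts <- function(fasta_file, structure_file) {
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  info <- utils::read.delim(structure_file, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = c("", "NA"))
  info$utr5_end <- suppressWarnings(as.integer(info$utr5_end))
  info$cds_end <- suppressWarnings(as.integer(info$cds_end))
  transcriptome(seqs, info)
}

#' Write a transcriptome to FASTA + structure table
#'
#' Inverse of [load_transcripts()]; round-trips byte-identically.
#' @param txome a [transcriptome()].
#' @param fasta_file,structure_file output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(txome, fasta_file, structure_file) {
  seqs <- Biostrings::DNAStringSet(txome$sequence)
  Biostrings::writeXStringSet(seqs, fasta_file)
  tab <- txome$info[, c("transcript_id", "gene_id", "biotype", "utr5_end", "cds_end")]
  tab$utr5_end <- ifelse(is.na(tab$utr5_end), "", as.character(tab$utr5_end))
  tab$cds_end <- ifelse(is.na(tab$cds_end), "", as.character(tab$cds_end))
  utils::write.table(tab, structure_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_file, structure_file))
}

#' Import transcript structure from a transcript-space GTF/GFF
#'
#' Convenience importer for annotations already projected onto transcript
#' coordinates (one "chromosome" per transcript, features `exon`, `CDS`,
#' `five_prime_utr`, `three_prime_utr` keyed by `transcript_id`). GTF's
#' 1-based closed intervals are converted to 0-based half-open at this
#' boundary. Transcripts with a CDS feature are `coding`, others `noncoding`.
#'
#' @param gtf_file path to the GTF/GFF file.
#' @param fasta_file path to the matching transcript FASTA.
#' @return a [transcriptome()].
#' @export
import_transcripts_gtf <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file)
  md <- S4Vectors::mcols(gr)
  tx_id <- as.character(md$transcript_id)
  type <- as.character(md$type)
  gene <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tx_id
  ids <- unique(tx_id)
  rows <- lapply(ids, function(id) {
    sel <- tx_id == id
    cds <- gr[sel & type == "CDS"]
    g <- gene[sel][1]
    if (length(cds) == 0L) {
      data.frame(transcript_id = id, gene_id = g, biotype = "noncoding",
                 utr5_end = NA_integer_, cds_end = NA_integer_)
    } else {
      data.frame(transcript_id = id, gene_id = g, biotype = "coding",
                 utr5_end = min(IRanges::start(cds)) - 1L,
                 cds_end = max(IRanges::end(cds)))
    }
  })
  info <- do.call(rbind, rows)
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  transcriptome(seqs, info)
}

#' Region intervals of a transcript
#'
#' @param txome a [transcriptome()].
#' @param transcript_id transcript to query.
#' @return list with 0-based half-open intervals `utr5`, `cds`, `utr3`
#'   (each `c(start, end)`, `NULL` when empty/noncoding) and `length`.
#' @export
tx_regions <- function(txome, transcript_id) {
  i <- match(transcript_id, txome$info$transcript_id)
  if (is.na(i)) stop("unknown transcript '", transcript_id, "'")
  len <- txome$info$length[i]
  if (txome$info$biotype[i] == "noncoding") {
    return(list(utr5 = NULL, cds = NULL, utr3 = NULL, length = len))
  }
  u5 <- txome$info$utr5_end[i]; ce <- txome$info$cds_end[i]
  list(
    utr5 = if (u5 > 0) c(0L, u5) else NULL,
    cds = c(u5, ce),
    utr3 = if (ce < len) c(ce, len) else NULL,
    length = len
  )
}
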