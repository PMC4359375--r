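AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Pooled amino-acid frequencies of a peptide set
#'
#' Residues are pooled across all peptides (not averaged per peptide) and
#' frequencies over the 20 standard amino acids returned.
#'
#' @param peptides character vector of peptides over the 20-letter alphabet.
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_frequencies <- function(peptides) {
  chars <- unlist(strsplit(peptides, ""), use.names = FALSE)
  if (length(chars) == 0L) stop("aa_frequencies: empty peptide pool")
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad)) {
    stop("aa_frequencies: unknown residue(s): ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(chars, levels = AA_STANDARD))
  freq <- as.numeric(counts) / length(chars)
  names(freq) <- AA_STANDARD
  freq
}

#' Random-expected amino-acid frequencies from nucleotide composition
#'
#' Null amino-acid usage under random coding sequence with the given
#' nucleotide composition: each codon's probability is the product of its
#' three nucleotide frequencies; amino-acid probabilities sum synonymous
#' codons and are renormalized over the 61 sense codons (stops excluded).
#' Under uniform composition Met = 1/61 and Leu = 6/61.
#'
#' @param nucleotide_freqs named numeric vector over `A,C,G,T`, non-negative,
#'   summing to 1.
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
random_expected_frequencies <- function(nucleotide_freqs) {
  nt <- c("A", "C", "G", "T")
  if (!all(nt %in% names(nucleotide_freqs))) {
    stop("random_expected_frequencies: need frequencies named A, C, G, T")
  }
  f <- nucleotide_freqs[nt]
  if (any(f < 0) || abs(sum(f) - 1) > 1e-6) {
    stop("random_expected_frequencies: frequencies must be non-negative and sum to 1")
  }
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  p <- f[substr(codons, 1, 1)] * f[substr(codons, 2, 2)] * f[substr(codons, 3, 3)]
  sense <- code != "*"
  p <- p[sense]
  aa <- code[sense]
  total <- sum(p)
  if (total <= 0) stop("random_expected_frequencies: degenerate composition, no sense codon possible")
  freq <- vapply(AA_STANDARD, function(a) sum(p[aa == a]), numeric(1)) / total
  freq
}

#' Pooled nucleotide composition of a sequence set
#'
#' A/C/G/T frequencies pooled over all sequences (N bases excluded); the
#' input pool for [random_expected_frequencies()].
#'
#' @param sequences character vector of nucleotide sequences.
#' @return named numeric vector over `A,C,G,T`, summing to 1.
#' @export
nucleotide_frequencies <- function(sequences) {
  chars <- unlist(strsplit(toupper(sequences), ""), use.names = FALSE)
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0L) stop("nucleotide_frequencies: no ACGT bases")
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  freq <- as.numeric(counts) / length(chars)
  names(freq) <- c("A", "C", "G", "T")
  freq
}

#' Amino-acid composition table across peptide sets
#'
#' One row per amino acid: the random expectation from nucleotide
#' composition, the observed frequency in each peptide set, and (optionally)
#' each set's ratio to random.
#'
#' @param peptide_sets named list of character vectors of peptides
#'   (e.g. all CDSs, all smORFs, translated smORFs).
#' @param nucleotide_freqs composition for the random expectation (e.g. from
#'   [nucleotide_frequencies()] over the transcript pool).
#' @param ratio if `TRUE` append `<set>_vs_random` columns.
#' @return data.frame with columns `aa`, `random_expected`, one per set, and
#'   optional ratio columns.
#' @export
composition_table <- function(peptide_sets, nucleotide_freqs, ratio = TRUE) {
  if (is.null(names(peptide_sets)) || any(names(peptide_sets) == "")) {
    stop("composition_table: peptide_sets must be named")
  }
  rand <- random_expected_frequencies(nucleotide_freqs)
  out <- data.frame(aa = AA_STANDARD, random_expected = unname(rand))
  for (nm in names(peptide_sets)) {
    out[[nm]] <- unname(aa_frequencies(peptide_sets[[nm]]))
  }
  if (ratio) {
    for (nm in names(peptide_sets)) {
      out[[paste0(nm, "_vs_random")]] <- out[[nm]] / out$random_expected
    }
  }
  out
}
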