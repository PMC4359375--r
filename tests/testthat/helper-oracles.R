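# Independent brute-force oracles used to check the package's vectorized
# implementations. These stay deliberately naive (position-by-position scans,
# per-base arrays) and share no code with R/.

oracle_find_orfs <- function(sequence, min_aa = 11L,
                             mode = c("longest_per_stop", "all_starts")) {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  codon <- function(i) substr(sequence, i, i + 2L)
  hits <- list()
  for (i in seq_len(max(n - 2L, 0L))) {
    if (codon(i) != "ATG") next
    j <- i + 3L
    while (j <= n - 2L) {
      if (codon(j) %in% stops) {
        aa <- (j - i) %/% 3L
        if (aa >= min_aa) {
          hits[[length(hits) + 1L]] <- c(i - 1L, j + 2L, aa)
        }
        break
      }
      j <- j + 3L
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(), aa_length = integer()))
  }
  res <- as.data.frame(do.call(rbind, hits))
  names(res) <- c("start", "end", "aa_length")
  if (mode == "longest_per_stop") {
    res <- do.call(rbind, lapply(split(res, res$end), function(d) {
      d[which.min(d$start), , drop = FALSE]
    }))
  }
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_coverage <- function(feature, aln) {
  covered <- rep(FALSE, feature$end - feature$start)
  a <- aln[aln$transcript_id == feature$transcript_id, , drop = FALSE]
  for (k in seq_len(nrow(a))) {
    lo <- max(a$start[k], feature$start)
    hi <- min(a$start[k] + a$length[k], feature$end)
    if (hi > lo) covered[(lo - feature$start + 1L):(hi - feature$start)] <- TRUE
  }
  mean(covered)
}

oracle_count <- function(feature, anchors, multiplicity) {
  total <- 0L
  for (k in seq_along(anchors)) {
    if (!is.na(anchors[k]) && anchors[k] >= feature$start &&
        anchors[k] < feature$end) {
      total <- total + multiplicity[k]
    }
  }
  total
}

oracle_mean_conservation <- function(feature, blocks) {
  per_base <- rep(0, feature$end - feature$start)
  b <- blocks[blocks$space_id == feature$transcript_id, , drop = FALSE]
  for (k in seq_len(nrow(b))) {
    lo <- max(b$start[k], feature$start)
    hi <- min(b$end[k], feature$end)
    if (hi > lo) per_base[(lo - feature$start + 1L):(hi - feature$start)] <- b$score[k]
  }
  mean(per_base)
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
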