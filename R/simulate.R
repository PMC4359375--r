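SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
SENSE_NO_ATG <- setdiff(SENSE_CODONS, "ATG")
# offsets used when *emitting* reads (inverse of P-site assignment); 33-34 nt
# reads, which the analysis anchors at midpoints, are emitted with +14
GEN_OFFSETS <- c(`28` = 12L, `29` = 12L, `30` = 13L, `31` = 13L, `32` = 14L,
                 `33` = 14L, `34` = 14L)

#' Simulation configuration
#'
#' Parameters of the synthetic Poly-Ribo-Seq experiment: a transcriptome with
#' known translation truth, Poisson ribosome loading split into sub-polysomal
#' (<= 1 ribosome), small-polysome (2-6) and large-polysome (>= 7) fractions,
#' footprints of 28-34 nt with triplet phasing on translated ORFs, unphased
#' background on UTRs, 50-80 nt mRNA fragments, and conservation blocks with
#' high scores over translated ORFs against a low intergenic baseline.
#'
#' @param seed integer seed governing every random draw downstream.
#' @param n_canonical,n_smorf,n_ncrna transcript counts per class.
#' @param p_uorf fraction of coding 5'-UTRs carrying one embedded uORF.
#' @param translated_fraction named vector: probability that a canonical CDS,
#'   smORF CDS, uORF or ncORF is translated.
#' @param canonical_aa,smorf_aa,uorf_aa,ncorf_aa peptide-length ranges (aa).
#' @param ncorfs_per_ncrna range of embedded ORFs per ncRNA.
#' @param utr5_len,utr3_len UTR length ranges (nt).
#' @param copies_per_transcript mean mRNA copies per transcript at unit
#'   abundance.
#' @param abundance_sdlog lognormal sdlog of per-transcript abundance.
#' @param loading_rate_meanlog,loading_rate_sdlog lognormal parameters of the
#'   per-ORF ribosome-loading rate (translated main ORFs draw
#'   `min(capacity, 1 + Poisson(rate))` ribosomes per copy).
#' @param rate_scale multiplier on all loading/emission rates (0 switches
#'   translation signal off).
#' @param uorf_rate_meanlog,uorf_rate_sdlog lognormal parameters of the
#'   per-copy footprint emission weight of translated uORFs/secondary ORFs.
#' @param background_rate unphased background footprint weight per nt per
#'   copy on UTRs and non-ORF ncRNA sequence.
#' @param utr5_background_mult multiplier on `background_rate` for 5'-UTRs
#'   (scanning-ribosome occupancy exceeds 3'-UTR background).
#' @param background_load_p probability an untranslated mRNA copy carries one
#'   (monosome) ribosome.
#' @param frame_fidelity probability a signal P-site sits at a codon start
#'   (frame 0); the rest is split evenly over +/-1 nt.
#' @param footprint_length_probs named probabilities over read lengths 28-34.
#' @param mrna_fragment_range mRNA fragment length range (nt).
#' @param ribosome_spacing nt of ORF per additional ribosome (capacity model).
#' @param small_fraction_range,large_fraction_min ribosome-count windows
#'   defining the polysome fractions.
#' @param library_size_fp,library_size_mrna reads per footprint fraction /
#'   mRNA control library.
#' @param conservation_high,conservation_low Beta(shape1, shape2) parameters
#'   of block scores over translated ORFs (mean 0.66) and elsewhere
#'   (90th percentile 0.55).
#' @param intergenic_n size of the simulated intergenic score sample.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_canonical = 300L, n_smorf = 150L, n_ncrna = 50L,
                       p_uorf = 0.4,
                       translated_fraction = c(canonical = 0.8, smorf = 0.8,
                                               uorf = 0.2, ncorf = 0.3),
                       canonical_aa = c(150L, 500L), smorf_aa = c(11L, 100L),
                       uorf_aa = c(11L, 30L), ncorf_aa = c(11L, 80L),
                       ncorfs_per_ncrna = c(1L, 3L),
                       utr5_len = c(30L, 200L), utr3_len = c(60L, 300L),
                       copies_per_transcript = 20,
                       abundance_sdlog = 0.5,
                       loading_rate_meanlog = log(3), loading_rate_sdlog = 0.4,
                       rate_scale = 1,
                       uorf_rate_meanlog = 0, uorf_rate_sdlog = 0.4,
                       background_rate = 2e-4, utr5_background_mult = 3,
                       background_load_p = 0.1,
                       frame_fidelity = 0.85,
                       footprint_length_probs = c(`28` = 0.15, `29` = 0.20,
                                                  `30` = 0.22, `31` = 0.18,
                                                  `32` = 0.13, `33` = 0.07,
                                                  `34` = 0.05),
                       mrna_fragment_range = c(50L, 80L),
                       ribosome_spacing = 80L,
                       small_fraction_range = c(2L, 6L),
                       large_fraction_min = 7L,
                       library_size_fp = 2e5, library_size_mrna = 2e5,
                       conservation_high = c(8, 4.121),
                       conservation_low = c(2, 4.429),
                       intergenic_n = 500L) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  if (abs(sum(footprint_length_probs) - 1) > 1e-8) {
    stop("sim_config: footprint_length_probs must sum to 1")
  }
  stopifnot(ribosome_spacing > 0,
            small_fraction_range[1] <= small_fraction_range[2],
            large_fraction_min > small_fraction_range[2],
            mrna_fragment_range[1] <= mrna_fragment_range[2],
            frame_fidelity >= 0, frame_fidelity <= 1,
            p_uorf >= 0, p_uorf <= 1, rate_scale >= 0)
  structure(cfg, class = "sim_config")
}

#' Ribosome capacity of an ORF
#'
#' Maximum ribosomes simultaneously bound: one at the start codon plus one
#' per (possibly partial) spacing interval, `1 + ceiling(L / spacing)` — the
#' convention under which a 303-nt smORF at 80-nt spacing holds 5 ribosomes.
#' `mode = "strict_packing"` instead fits whole footprints positionally,
#' `1 + floor((L - footprint) / spacing)`, reflecting tighter packing
#' arguments (gives 4 for the same smORF).
#'
#' @param orf_length ORF length in nt (>= 3), stop codon included.
#' @param spacing nt per additional ribosome (default 80).
#' @param mode `"start_plus_intervals"` (default) or `"strict_packing"`.
#' @param footprint footprint size used by strict packing (default 28 nt).
#' @return integer ribosome count (vectorized over `orf_length`).
#' @export
ribosome_capacity <- function(orf_length, spacing = 80L,
                              mode = c("start_plus_intervals", "strict_packing"),
                              footprint = 28L) {
  mode <- match.arg(mode)
  if (any(orf_length < 3) || spacing <= 0) {
    stop("ribosome_capacity: need orf_length >= 3 and spacing > 0")
  }
  if (mode == "start_plus_intervals") {
    as.integer(1L + ceiling(orf_length / spacing))
  } else {
    as.integer(pmax(1L, 1L + floor((orf_length - footprint) / spacing)))
  }
}

# -- sequence construction helpers -------------------------------------------

rand_nt <- function(n) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

make_orf_seq <- function(aa) { # chars; ATG + (aa-1) sense non-ATG codons + stop
  body <- if (aa > 1) sample(SENSE_NO_ATG, aa - 1L, replace = TRUE) else character(0)
  unlist(strsplit(c("ATG", body, sample(STOP_CODONS, 1L)), ""), use.names = FALSE)
}

# mutate the G of any ATG triplet whose G lies outside all protected
# intervals (0-based half-open), so background sequence seeds no spurious ORFs
scrub_atg <- function(chars, protected = NULL) {
  n <- length(chars)
  if (n < 3L) return(chars)
  is_atg <- chars[1:(n - 2L)] == "A" & chars[2:(n - 1L)] == "T" & chars[3:n] == "G"
  pos <- which(is_atg) # 1-based triplet starts
  if (length(pos) == 0L) return(chars)
  g_pos0 <- pos + 1L # 0-based position of the G
  if (!is.null(protected) && nrow(protected) > 0) {
    inside <- rep(FALSE, length(g_pos0))
    for (k in seq_len(nrow(protected))) {
      inside <- inside | (g_pos0 >= protected$start[k] & g_pos0 < protected$end[k])
    }
    g_pos0 <- g_pos0[!inside]
  }
  chars[g_pos0 + 1L] <- "C"
  chars
}

#' Simulate a transcriptome with known translation truth
#'
#' Builds canonical (> 100 aa) and smORF (<= 100 aa) coding transcripts,
#' ncRNAs seeded with qualifying AUG ORFs, and uORFs embedded in a configured
#' fraction of 5'-UTRs. Background sequence is scrubbed of AUG triplets
#' outside embedded ORFs so every ground-truth ORF is re-discoverable at its
#' exact coordinates. Each ORF gets a translated flag and loading/emission
#' rate; each transcript an abundance.
#'
#' @param config a [sim_config()]; consumes the RNG from `config$seed`.
#' @return list of class `sim_truth`: `txome` ([transcriptome()]), `orfs`
#'   (truth table: `feature_id`, `transcript_id`, `start`, `end`, `category`,
#'   `aa_length`, `translated`, `rate`, `is_main`), `transcripts`
#'   (`transcript_id`, `abundance`, `main_orf`), `config`.
#' @export
simulate_transcriptome <- function(config) {
  set.seed(config$seed)
  seqs <- character(0)
  info <- list(); orfs <- list(); txrows <- list()
  tf <- config$translated_fraction

  add_coding <- function(id, gene, aa, kind) {
    cds_chars <- make_orf_seq(aa)
    cds_len <- length(cds_chars)
    has_uorf <- stats::runif(1) < config$p_uorf
    uorf_aa <- if (has_uorf) sample(config$uorf_aa[1]:config$uorf_aa[2], 1L) else 0L
    uorf_nt <- if (has_uorf) 3L * (uorf_aa + 1L) else 0L
    u5_min <- max(config$utr5_len[1], uorf_nt + 24L)
    u5_len <- sample(u5_min:max(config$utr5_len[2], u5_min), 1L)
    u3_len <- sample(config$utr3_len[1]:config$utr3_len[2], 1L)
    u5 <- rand_nt(u5_len)
    uorf_row <- NULL
    if (has_uorf) {
      off <- sample(15:(u5_len - uorf_nt - 3L), 1L)
      u5[(off + 1L):(off + uorf_nt)] <- make_orf_seq(uorf_aa)
      u5 <- scrub_atg(u5, data.frame(start = off, end = off + uorf_nt))
      uorf_row <- data.frame(
        feature_id = paste0(id, "_uORF1"), transcript_id = id,
        start = off, end = off + uorf_nt, category = "uorf",
        aa_length = uorf_aa,
        translated = stats::runif(1) < tf[["uorf"]],
        rate = stats::rlnorm(1, config$uorf_rate_meanlog, config$uorf_rate_sdlog) *
          config$rate_scale,
        is_main = FALSE
      )
    } else {
      u5 <- scrub_atg(u5)
    }
    u3 <- rand_nt(u3_len)
    seqs[[id]] <<- paste(c(u5, cds_chars, u3), collapse = "")
    info[[length(info) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gene, biotype = "coding",
      utr5_end = u5_len, cds_end = u5_len + cds_len
    )
    main <- data.frame(
      feature_id = paste0(id, "_CDS"), transcript_id = id,
      start = u5_len, end = u5_len + cds_len,
      category = if (aa <= 100L) "smorf_cds" else "canonical_cds",
      aa_length = aa,
      translated = stats::runif(1) < tf[[kind]],
      rate = stats::rlnorm(1, config$loading_rate_meanlog,
                           config$loading_rate_sdlog) * config$rate_scale,
      is_main = TRUE
    )
    orfs[[length(orfs) + 1L]] <<- main
    if (!is.null(uorf_row)) orfs[[length(orfs) + 1L]] <<- uorf_row
    txrows[[length(txrows) + 1L]] <<- data.frame(
      transcript_id = id,
      abundance = stats::rlnorm(1, 0, config$abundance_sdlog),
      main_orf = main$feature_id
    )
  }

  for (i in seq_len(config$n_canonical)) {
    add_coding(sprintf("can%04d", i), sprintf("gcan%04d", i),
               sample(config$canonical_aa[1]:config$canonical_aa[2], 1L),
               "canonical")
  }
  for (i in seq_len(config$n_smorf)) {
    add_coding(sprintf("smo%04d", i), sprintf("gsmo%04d", i),
               sample(config$smorf_aa[1]:config$smorf_aa[2], 1L), "smorf")
  }
  for (i in seq_len(config$n_ncrna)) {
    id <- sprintf("ncr%04d", i)
    k <- sample(config$ncorfs_per_ncrna[1]:config$ncorfs_per_ncrna[2], 1L)
    chars <- rand_nt(sample(20:60, 1L)) # leading spacer
    protected <- data.frame(start = integer(), end = integer())
    rows <- list()
    for (j in seq_len(k)) {
      aa <- sample(config$ncorf_aa[1]:config$ncorf_aa[2], 1L)
      oseq <- make_orf_seq(aa)
      ostart <- length(chars)
      chars <- c(chars, oseq, rand_nt(sample(15:50, 1L)))
      protected <- rbind(protected,
                         data.frame(start = ostart, end = ostart + length(oseq)))
      rows[[j]] <- data.frame(
        feature_id = sprintf("%s_ORF%d", id, j), transcript_id = id,
        start = ostart, end = ostart + length(oseq), category = "ncorf",
        aa_length = aa,
        translated = stats::runif(1) < tf[["ncorf"]],
        rate = stats::rlnorm(1, config$loading_rate_meanlog,
                             config$loading_rate_sdlog) * config$rate_scale,
        is_main = FALSE
      )
    }
    chars <- c(chars, rand_nt(30L))
    chars <- scrub_atg(chars, protected)
    ncorf_rows <- do.call(rbind, rows)
    # the dominant translated ncORF drives polysome loading of the ncRNA
    tr <- which(ncorf_rows$translated)
    main_orf <- if (length(tr)) {
      mo <- tr[which.max(ncorf_rows$rate[tr])]
      ncorf_rows$is_main[mo] <- TRUE
      ncorf_rows$feature_id[mo]
    } else NA_character_
    seqs[[id]] <- paste(chars, collapse = "")
    info[[length(info) + 1L]] <- data.frame(
      transcript_id = id, gene_id = sprintf("gncr%04d", i),
      biotype = "noncoding", utr5_end = NA_integer_, cds_end = NA_integer_
    )
    orfs[[length(orfs) + 1L]] <- ncorf_rows
    txrows[[length(txrows) + 1L]] <- data.frame(
      transcript_id = id,
      abundance = stats::rlnorm(1, 0, config$abundance_sdlog),
      main_orf = main_orf
    )
  }

  txome <- transcriptome(unlist(seqs),
                         do.call(rbind, info))
  orfs <- do.call(rbind, orfs); rownames(orfs) <- NULL
  transcripts <- do.call(rbind, txrows); rownames(transcripts) <- NULL
  structure(list(txome = txome, orfs = orfs, transcripts = transcripts,
                 config = config), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$txome$info), "transcripts,", nrow(x$orfs),
      "truth ORFs (", sum(x$orfs$translated), "translated )\n")
  invisible(x)
}

#' Simulate polysome loading of mRNA copies
#'
#' Each transcript spawns `Poisson(copies_per_transcript * abundance)` mRNA
#' copies. Copies of transcripts with a translated main ORF carry
#' `min(capacity, 1 + Poisson(rate))` ribosomes; untranslated copies carry
#' 0 or 1 (background monosome). Copies are labelled `subpolysomal` (<= 1),
#' `small_polysome` (2-6) or `large_polysome` (>= 7).
#'
#' @param sim a `sim_truth` from [simulate_transcriptome()].
#' @param seed optional seed (otherwise continues the current RNG stream).
#' @return data.frame (`transcript_id`, `ribosome_count`, `fraction`), one
#'   row per mRNA copy.
#' @export
simulate_polysome_loading <- function(sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$config
  tx <- sim$transcripts
  n_copies <- stats::rpois(nrow(tx), cfg$copies_per_transcript * tx$abundance)
  tx_id <- rep(tx$transcript_id, n_copies)
  main <- rep(tx$main_orf, n_copies)
  counts <- integer(length(tx_id))
  mo <- match(main, sim$orfs$feature_id)
  translated <- !is.na(mo) & sim$orfs$translated[mo]
  if (any(translated)) {
    rate <- sim$orfs$rate[mo[translated]]
    cap <- ribosome_capacity(sim$orfs$end[mo[translated]] -
                               sim$orfs$start[mo[translated]],
                             cfg$ribosome_spacing)
    counts[translated] <- pmin(cap, 1L + stats::rpois(sum(translated), rate))
  }
  counts[!translated] <- stats::rbinom(sum(!translated), 1L, cfg$background_load_p)
  fraction <- ifelse(counts >= cfg$large_fraction_min, "large_polysome",
                     ifelse(counts >= cfg$small_fraction_range[1] &
                              counts <= cfg$small_fraction_range[2],
                            "small_polysome", "subpolysomal"))
  data.frame(transcript_id = tx_id, ribosome_count = counts, fraction = fraction)
}

#' Simulate ribosome footprints for one polysome fraction
#'
#' Allocates the fraction's library over emission sources by multinomial
#' sampling: each translated main ORF emits proportionally to the summed
#' ribosome counts of the transcript's copies in the fraction; translated
#' secondary ORFs (uORFs, extra ncORFs) emit at their own per-copy rate;
#' UTRs and non-ORF ncRNA sequence emit unphased background at
#' `background_rate` per nt per copy (5'-UTRs multiplied by
#' `utr5_background_mult`). Signal P-sites sit at codon starts with
#' probability `frame_fidelity`, else are jittered +/-1 nt; read 5' ends are
#' P-site minus the length-dependent offset. Signal reads may overhang the
#' ORF 5' start (footprints at the start codon protect upstream sequence) but
#' never its 3' end, so with zero background a downstream UTR carries no
#' signal. Out-of-bounds reads are dropped, so the returned library can be
#' marginally smaller than requested.
#'
#' @param sim a `sim_truth`.
#' @param loading copies table from [simulate_polysome_loading()].
#' @param fraction `"small_polysome"` or `"large_polysome"`.
#' @param library_size reads to draw (default `config$library_size_fp`).
#' @param seed optional seed.
#' @return alignment data.frame (see [alignments()]).
#' @export
simulate_footprints <- function(sim, loading, fraction = "small_polysome",
                                library_size = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$config
  if (is.null(library_size)) library_size <- cfg$library_size_fp
  copies <- loading[loading$fraction == fraction, , drop = FALSE]
  if (nrow(copies) == 0L || library_size == 0) return(alignments())
  n_f <- table(copies$transcript_id)
  sum_counts <- tapply(copies$ribosome_count, copies$transcript_id, sum)

  txinfo <- sim$txome$info
  src <- list()
  add_src <- function(tx, start, end, type, weight) {
    src[[length(src) + 1L]] <<- data.frame(
      transcript_id = tx, start = start, end = end, type = type, weight = weight)
  }
  for (tx in names(n_f)) {
    i <- match(tx, txinfo$transcript_id)
    nf <- as.numeric(n_f[[tx]])
    txlen <- txinfo$length[i]
    tx_orfs <- sim$orfs[sim$orfs$transcript_id == tx, , drop = FALSE]
    main <- tx_orfs[tx_orfs$is_main & tx_orfs$translated, , drop = FALSE]
    if (nrow(main) == 1L) {
      add_src(tx, main$start, main$end, "orf", as.numeric(sum_counts[[tx]]))
    }
    sec <- tx_orfs[!tx_orfs$is_main & tx_orfs$translated, , drop = FALSE]
    for (j in seq_len(nrow(sec))) {
      add_src(tx, sec$start[j], sec$end[j], "orf", sec$rate[j] * nf)
    }
    if (txinfo$biotype[i] == "coding") {
      u5 <- txinfo$utr5_end[i]; ce <- txinfo$cds_end[i]
      if (u5 > 0) {
        add_src(tx, 0L, u5, "bg",
                cfg$background_rate * cfg$utr5_background_mult * u5 * nf)
      }
      if (ce < txlen) {
        add_src(tx, ce, txlen, "bg", cfg$background_rate * (txlen - ce) * nf)
      }
    } else {
      add_src(tx, 0L, txlen, "bg", cfg$background_rate * txlen * nf)
    }
  }
  src <- do.call(rbind, src)
  src <- src[src$weight > 0, , drop = FALSE]
  if (nrow(src) == 0L) return(alignments())
  n_per <- as.vector(stats::rmultinom(1, library_size, src$weight))

  lens_all <- as.integer(names(cfg$footprint_length_probs))
  out <- vector("list", nrow(src))
  for (s in seq_len(nrow(src))) {
    n <- n_per[s]
    if (n == 0L) next
    len <- sample(lens_all, n, replace = TRUE, prob = cfg$footprint_length_probs)
    off <- GEN_OFFSETS[as.character(len)]
    if (src$type[s] == "orf") {
      n_codons <- (src$end[s] - src$start[s]) %/% 3L
      psite <- src$start[s] + 3L * (sample.int(n_codons, n, replace = TRUE) - 1L)
      jit <- sample(c(0L, -1L, 1L), n, replace = TRUE,
                    prob = c(cfg$frame_fidelity, (1 - cfg$frame_fidelity) / 2,
                             (1 - cfg$frame_fidelity) / 2))
      psite <- psite + jit
    } else {
      psite <- src$start[s] + sample.int(src$end[s] - src$start[s], n,
                                         replace = TRUE) - 1L
    }
    rs <- psite - as.integer(off)
    txlen <- sim$txome$info$length[match(src$transcript_id[s],
                                         sim$txome$info$transcript_id)]
    keep <- rs >= 0L & rs + len <= txlen
    if (src$type[s] == "orf") {
      # elongating-ribosome footprints stay within the ORF 3' boundary, so a
      # translated ORF sheds no signal into the downstream UTR
      keep <- keep & (rs + len <= src$end[s])
    }
    if (!any(keep)) next
    out[[s]] <- data.frame(transcript_id = src$transcript_id[s],
                           start = rs[keep], length = len[keep])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(alignments())
  res <- do.call(rbind, out)
  alignments(res$transcript_id, res$start, res$length, 1L)
}

#' Simulate the total-mRNA fragment control library
#'
#' Fragments of 50-80 nt placed uniformly along transcripts, with counts
#' proportional to abundance times transcript length. Transcripts shorter
#' than the minimum fragment length are skipped with a warning.
#'
#' @param sim a `sim_truth`.
#' @param library_size fragments to draw (default `config$library_size_mrna`).
#' @param seed optional seed.
#' @return alignment data.frame.
#' @export
simulate_mrna_fragments <- function(sim, library_size = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$config
  if (is.null(library_size)) library_size <- cfg$library_size_mrna
  tx <- sim$transcripts
  txlen <- sim$txome$info$length[match(tx$transcript_id,
                                       sim$txome$info$transcript_id)]
  short <- txlen < cfg$mrna_fragment_range[1]
  if (any(short)) {
    warning("simulate_mrna_fragments: skipping ", sum(short),
            " transcript(s) shorter than the minimum fragment length")
  }
  w <- ifelse(short, 0, tx$abundance * txlen)
  if (sum(w) == 0 || library_size == 0) return(alignments())
  n_per <- as.vector(stats::rmultinom(1, library_size, w))
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    n <- n_per[i]
    if (n == 0L) next
    len <- sample(cfg$mrna_fragment_range[1]:cfg$mrna_fragment_range[2], n,
                  replace = TRUE)
    len <- pmin(len, txlen[i])
    start <- vapply(txlen[i] - len, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
    out[[i]] <- data.frame(transcript_id = tx$transcript_id[i],
                           start = start, length = len)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out)
  alignments(res$transcript_id, res$start, res$length, 1L)
}

#' Simulate conservation blocks and an intergenic score sample
#'
#' Tiles every transcript with non-overlapping blocks of 40-120 nt. Blocks
#' overlapping a translated truth ORF draw scores from the high Beta
#' distribution (mean 0.66); all other blocks and the separate intergenic
#' sample draw from the low Beta distribution (90th percentile 0.55).
#'
#' @param sim a `sim_truth`.
#' @param seed optional seed.
#' @return list: `blocks` (data.frame `space_id`, `start`, `end`, `score`)
#'   and `intergenic_scores` (numeric vector).
#' @export
simulate_conservation <- function(sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim$config
  hi <- cfg$conservation_high; lo <- cfg$conservation_low
  out <- list()
  for (i in seq_len(nrow(sim$txome$info))) {
    tx <- sim$txome$info$transcript_id[i]
    txlen <- sim$txome$info$length[i]
    starts <- integer(0); ends <- integer(0)
    pos <- 0L
    while (pos < txlen) {
      w <- sample(40:120, 1L)
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + w, txlen))
      pos <- pos + w
    }
    torfs <- sim$orfs[sim$orfs$transcript_id == tx & sim$orfs$translated, ,
                      drop = FALSE]
    hit <- rep(FALSE, length(starts))
    for (j in seq_len(nrow(torfs))) {
      hit <- hit | (starts < torfs$end[j] & ends > torfs$start[j])
    }
    score <- numeric(length(starts))
    score[hit] <- stats::rbeta(sum(hit), hi[1], hi[2])
    score[!hit] <- stats::rbeta(sum(!hit), lo[1], lo[2])
    out[[i]] <- data.frame(space_id = tx, start = starts, end = ends,
                           score = score)
  }
  list(blocks = do.call(rbind, out),
       intergenic_scores = stats::rbeta(cfg$intergenic_n, lo[1], lo[2]))
}

#' Run the full synthetic Poly-Ribo-Seq experiment
#'
#' Chains transcriptome construction, polysome loading, footprint libraries
#' for the small and large fractions, the total-mRNA control and the
#' conservation track, with stage seeds derived from `config$seed` so the
#' whole bundle is reproducible from one integer.
#'
#' @param config a [sim_config()].
#' @return list: `sim` (`sim_truth`), `loading`, `fp` (named list of
#'   alignment data.frames per fraction), `mrna`, `conservation`.
#' @export
simulate_experiment <- function(config) {
  sim <- simulate_transcriptome(config)
  loading <- simulate_polysome_loading(sim, seed = config$seed + 1L)
  fp <- list(
    small_polysome = simulate_footprints(sim, loading, "small_polysome",
                                         seed = config$seed + 2L),
    large_polysome = simulate_footprints(sim, loading, "large_polysome",
                                         seed = config$seed + 3L)
  )
  mrna <- simulate_mrna_fragments(sim, seed = config$seed + 4L)
  conservation <- simulate_conservation(sim, seed = config$seed + 5L)
  list(sim = sim, loading = loading, fp = fp, mrna = mrna,
       conservation = conservation)
}

#' Write a simulated experiment to the pipeline's on-disk formats
#'
#' FASTA + structure table, BED6 alignments per fraction and for the mRNA
#' control, scored conservation BED, and a truth TSV.
#'
#' @param experiment result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "transcripts.fa"),
    structure = file.path(dir, "transcripts.tsv"),
    fp_small = file.path(dir, "fp_small_polysome.bed"),
    fp_large = file.path(dir, "fp_large_polysome.bed"),
    mrna = file.path(dir, "mrna_fragments.bed"),
    conservation = file.path(dir, "conservation.bed"),
    truth = file.path(dir, "truth_orfs.tsv")
  )
  write_transcripts(experiment$sim$txome, paths["fasta"], paths["structure"])
  write_alignments_bed(experiment$fp$small_polysome, paths["fp_small"])
  write_alignments_bed(experiment$fp$large_polysome, paths["fp_large"])
  write_alignments_bed(experiment$mrna, paths["mrna"])
  write_conservation_bed(experiment$conservation$blocks, paths["conservation"])
  utils::write.table(experiment$sim$orfs, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
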