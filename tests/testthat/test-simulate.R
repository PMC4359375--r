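test_that("ribosome capacity reproduces the smORF worked example", {
  expect_equal(ribosome_capacity(303), 5L)
  expect_equal(ribosome_capacity(80), 2L)
  expect_equal(ribosome_capacity(160), 3L)
  expect_equal(ribosome_capacity(303, mode = "strict_packing"), 4L)
  expect_error(ribosome_capacity(2), "orf_length")
})

test_that("transcriptome simulation is deterministic and self-consistent", {
  cfg <- tiny_config(seed = 42)
  s1 <- simulate_transcriptome(cfg)
  s2 <- simulate_transcriptome(cfg)
  expect_identical(s1$txome$sequence, s2$txome$sequence)
  expect_identical(s1$orfs, s2$orfs)
  expect_identical(s1$transcripts, s2$transcripts)

  no_nc <- simulate_transcriptome(tiny_config(seed = 42, n_ncrna = 0L))
  expect_false(any(no_nc$txome$info$biotype == "noncoding"))

  # every truth ORF is re-discovered at its exact coordinates (all_starts
  # mode: a truth ORF nested inside a longer same-stop ORF is still an AUG
  # ORF, which longest_per_stop deliberately collapses)
  p_all <- orf_params(report_mode = "all_starts")
  found <- list()
  for (tx in s1$txome$info$transcript_id) {
    bt <- s1$txome$info$biotype[s1$txome$info$transcript_id == tx]
    found[[tx]] <- if (bt == "coding") {
      reg <- tx_regions(s1$txome, tx)
      rbind(discover_uorfs(s1$txome, tx, p_all)[, c("transcript_id", "start", "end")],
            data.frame(transcript_id = tx, start = reg$cds[1], end = reg$cds[2]))
    } else {
      discover_ncorfs(s1$txome, tx, p_all)[, c("transcript_id", "start", "end")]
    }
  }
  found <- do.call(rbind, found)
  fkey <- paste(found$transcript_id, found$start, found$end)
  tkey <- paste(s1$orfs$transcript_id, s1$orfs$start, s1$orfs$end)
  expect_true(all(tkey %in% fkey))

  # CDS length classes respect the smORF boundary
  cds <- s1$orfs[s1$orfs$category %in% c("canonical_cds", "smorf_cds"), ]
  expect_true(all(cds$aa_length[cds$category == "smorf_cds"] <= 100))
  expect_true(all(cds$aa_length[cds$category == "canonical_cds"] > 100))
})

test_that("polysome loading respects capacity and fraction windows", {
  cfg <- tiny_config(seed = 43)
  sim <- simulate_transcriptome(cfg)
  loading <- simulate_polysome_loading(sim, seed = 44)
  expect_true(all(loading$fraction[loading$ribosome_count <= 1] == "subpolysomal"))
  expect_true(all(loading$fraction[loading$ribosome_count >= 2 &
                                     loading$ribosome_count <= 6] == "small_polysome"))
  expect_true(all(loading$fraction[loading$ribosome_count >= 7] == "large_polysome"))

  # counts never exceed the main ORF's capacity
  main <- sim$orfs[sim$orfs$is_main, ]
  cap <- ribosome_capacity(main$end - main$start, cfg$ribosome_spacing)
  names(cap) <- main$transcript_id
  with_main <- loading[loading$transcript_id %in% main$transcript_id, ]
  expect_true(all(with_main$ribosome_count <= cap[with_main$transcript_id]))

  # smORF-only transcripts (capacity <= 5) never reach the large fraction
  smorf_tx <- main$transcript_id[main$category == "smorf_cds"]
  expect_false(any(loading$fraction[loading$transcript_id %in% smorf_tx] ==
                     "large_polysome"))

  # rate 0 and no background load: nothing beyond the sub-polysomal pool
  quiet <- simulate_transcriptome(tiny_config(seed = 45, rate_scale = 0))
  quiet_loading <- simulate_polysome_loading(
    structure(list(txome = quiet$txome, orfs = quiet$orfs,
                   transcripts = quiet$transcripts,
                   config = tiny_config(seed = 45, rate_scale = 0,
                                        background_load_p = 0)),
              class = "sim_truth"), seed = 46)
  expect_true(all(quiet_loading$fraction == "subpolysomal"))
})

test_that("footprints land in bounds, in the right fraction, with phased signal", {
  cfg <- tiny_config(seed = 47)
  sim <- simulate_transcriptome(cfg)
  loading <- simulate_polysome_loading(sim, seed = 48)
  fp <- simulate_footprints(sim, loading, "small_polysome", seed = 49)

  txlen <- sim$txome$info$length
  names(txlen) <- sim$txome$info$transcript_id
  expect_true(all(fp$start >= 0))
  expect_true(all(fp$start + fp$length <= txlen[fp$transcript_id]))
  expect_true(all(fp$length %in% 28:34))

  # only transcripts with copies in the fraction emit
  in_frac <- unique(loading$transcript_id[loading$fraction == "small_polysome"])
  expect_true(all(fp$transcript_id %in% in_frac))

  # perfect fidelity, no background: every translated ORF is pure frame 0
  cfg1 <- tiny_config(seed = 50, frame_fidelity = 1, background_rate = 0)
  sim1 <- simulate_transcriptome(cfg1)
  load1 <- simulate_polysome_loading(sim1, seed = 51)
  fp1 <- simulate_footprints(sim1, load1, "small_polysome", seed = 52)
  torfs <- sim1$orfs[sim1$orfs$translated, ]
  checked <- 0L
  for (i in seq_len(nrow(torfs))) {
    fs <- frame_distribution(torfs[i, ], fp1)
    if (fs$total >= 20) {
      expect_equal(fs$fractions, c(1, 0, 0))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5)

  # no background: 3'-UTR background features carry zero coverage
  feats1 <- discover_features(sim1$txome)
  utr3 <- feats1[feats1$category == "utr3_background", ]
  covs <- vapply(seq_len(nrow(utr3)), function(i)
    coverage_fraction(utr3[i, ], fp1), numeric(1))
  expect_true(all(covs == 0))
})

test_that("frame fidelity is recovered from deeply covered ORFs", {
  cfg <- sim_config(seed = 53, n_canonical = 10L, n_smorf = 5L, n_ncrna = 0L,
                    p_uorf = 0, library_size_fp = 1.5e5,
                    library_size_mrna = 1e4, intergenic_n = 50L)
  sim <- simulate_transcriptome(cfg)
  loading <- simulate_polysome_loading(sim, seed = 54)
  fp <- simulate_footprints(sim, loading, "small_polysome", seed = 55)
  torfs <- sim$orfs[sim$orfs$translated & sim$orfs$is_main, ]
  checked <- 0L
  for (i in seq_len(nrow(torfs))) {
    fs <- frame_distribution(torfs[i, ], fp)
    if (fs$total >= 2000) {
      expect_lt(abs(fs$fractions[1] - cfg$frame_fidelity), 0.05)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 3)
})

test_that("mRNA fragments respect the length range and tile uniformly", {
  cfg <- tiny_config(seed = 56)
  sim <- simulate_transcriptome(cfg)
  mrna <- simulate_mrna_fragments(sim, seed = 57)
  expect_true(all(mrna$length >= 50 & mrna$length <= 80))
  txlen <- sim$txome$info$length
  names(txlen) <- sim$txome$info$transcript_id
  expect_true(all(mrna$start >= 0 & mrna$start + mrna$length <= txlen[mrna$transcript_id]))

  m2 <- simulate_mrna_fragments(sim, seed = 57)
  expect_identical(mrna, m2)

  # flat coverage on one deep transcript: no 100-nt window deviates > 25%
  one <- transcriptome(
    c(big = paste(rand_seq <- sample(c("A", "C", "G", "T"), 2000, TRUE),
                  collapse = "")),
    data.frame(transcript_id = "big", gene_id = "g", biotype = "coding",
               utr5_end = 0L, cds_end = 1998L))
  sim_one <- structure(list(
    txome = one,
    orfs = data.frame(),
    transcripts = data.frame(transcript_id = "big", abundance = 1,
                             main_orf = NA_character_),
    config = tiny_config(seed = 58)), class = "sim_truth")
  deep <- simulate_mrna_fragments(sim_one, library_size = 2000 * 50 / 65,
                                  seed = 59)
  covv <- integer(2000)
  for (k in seq_len(nrow(deep))) {
    covv[(deep$start[k] + 1L):(deep$start[k] + deep$length[k])] <-
      covv[(deep$start[k] + 1L):(deep$start[k] + deep$length[k])] + 1L
  }
  centers <- seq(200, 1800, by = 100) # away from edge ramps
  win <- vapply(centers, function(c0) mean(covv[(c0 - 50):(c0 + 49)]), numeric(1))
  expect_true(all(abs(win - mean(win)) / mean(win) < 0.25))

  short <- structure(list(
    txome = transcriptome(c(s = strrep("A", 30)),
                          data.frame(transcript_id = "s", gene_id = "g",
                                     biotype = "noncoding",
                                     utr5_end = NA_integer_, cds_end = NA_integer_)),
    orfs = data.frame(),
    transcripts = data.frame(transcript_id = "s", abundance = 1,
                             main_orf = NA_character_),
    config = tiny_config(seed = 60)), class = "sim_truth")
  expect_warning(simulate_mrna_fragments(short, library_size = 10, seed = 61),
                 "shorter than the minimum")
})

test_that("conservation blocks separate translated ORFs from background", {
  cfg <- tiny_config(seed = 62)
  sim <- simulate_transcriptome(cfg)
  cons <- simulate_conservation(sim, seed = 63)
  expect_true(all(cons$blocks$score >= 0 & cons$blocks$score <= 1))
  expect_true(all(cons$intergenic_scores >= 0 & cons$intergenic_scores <= 1))
  cons2 <- simulate_conservation(sim, seed = 63)
  expect_identical(cons, cons2)

  # over 10 seeds, >= 80% of translated ORFs clear the intergenic cutoff
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    simi <- simulate_transcriptome(tiny_config(seed = 700 + s))
    consi <- simulate_conservation(simi, seed = 800 + s)
    cutoff <- conservation_threshold(consi$intergenic_scores)
    torfs <- simi$orfs[simi$orfs$translated, ]
    sc <- vapply(seq_len(nrow(torfs)), function(i)
      mean_conservation(data.frame(transcript_id = torfs$transcript_id[i],
                                   start = torfs$start[i], end = torfs$end[i]),
                        data.frame(space_id = consi$blocks$space_id,
                                   start = consi$blocks$start,
                                   end = consi$blocks$end,
                                   score = consi$blocks$score)),
      numeric(1))
    hits <- hits + sum(sc >= cutoff)
    total <- total + length(sc)
  }
  expect_gte(hits / total, 0.8)
})

test_that("the experiment bundle writes and re-reads through standard formats", {
  cfg <- tiny_config(seed = 64)
  ex <- simulate_experiment(cfg)
  dir <- file.path(tempdir(), "simout")
  paths <- write_experiment(ex, dir)
  expect_true(all(file.exists(paths)))

  txome <- load_transcripts(paths["fasta"], paths["structure"])
  expect_identical(txome$sequence, ex$sim$txome$sequence)
  fp <- read_alignments_bed(paths["fp_small"])
  expect_equal(nrow(fp), nrow(ex$fp$small_polysome))
  truth <- utils::read.delim(paths["truth"])
  expect_equal(nrow(truth), nrow(ex$sim$orfs))
  unlink(dir, recursive = TRUE)
})
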