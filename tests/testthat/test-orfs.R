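test_that("find_orfs handles minimal constructions and the length filter", {
  s <- paste0("ATG", strrep("GCT", 10), "TAA") # 36 nt, 11 aa
  hit <- find_orfs(s, orf_params(min_aa = 11))
  expect_equal(hit, data.frame(start = 0L, end = 36L, aa_length = 11L))
  expect_equal(nrow(find_orfs(s, orf_params(min_aa = 12))), 0L)

  # codons containing N never match start or stop
  expect_equal(nrow(find_orfs(paste0("ATN", strrep("GCT", 10), "TAA"),
                              orf_params(min_aa = 1))), 0L)
  expect_equal(nrow(find_orfs(paste0("ATG", strrep("GCT", 10), "TAN"),
                              orf_params(min_aa = 1))), 0L)
})

test_that("find_orfs agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_sequence(500)
    for (mode in c("longest_per_stop", "all_starts")) {
      got <- find_orfs(s, orf_params(min_aa = 5, report_mode = mode))
      want <- oracle_find_orfs(s, min_aa = 5, mode = mode)
      expect_equal(got, want, info = paste("seq", i, mode))
    }
  }
})

test_that("all_starts output is a superset of longest_per_stop output", {
  set.seed(202)
  for (i in 1:25) {
    s <- random_sequence(400)
    all_s <- find_orfs(s, orf_params(min_aa = 3, report_mode = "all_starts"))
    longest <- find_orfs(s, orf_params(min_aa = 3))
    key_all <- paste(all_s$start, all_s$end)
    key_lng <- paste(longest$start, longest$end)
    expect_true(all(key_lng %in% key_all))
    # one ORF per stop in longest mode
    expect_false(any(duplicated(longest$end)))
  }
})

test_that("annotated CDSs classify as smORF at most 100 aa, canonical above", {
  seqs <- c(a = strrep("A", 400), b = strrep("A", 400), c = strrep("A", 100))
  info <- data.frame(transcript_id = c("a", "b", "c"), gene_id = "g",
                     biotype = "coding",
                     utr5_end = c(0L, 0L, 0L),
                     cds_end = c(303L, 306L, 60L))
  txome <- transcriptome(seqs, info)
  expect_equal(classify_annotated_cds(txome, "a"), "smorf_cds")     # 100 aa
  expect_equal(classify_annotated_cds(txome, "b"), "canonical_cds") # 101 aa
  expect_equal(classify_annotated_cds(txome, "c"), "smorf_cds")     # 19 aa
  nc <- transcriptome(c(n = strrep("A", 50)),
                      data.frame(transcript_id = "n", gene_id = "g",
                                 biotype = "noncoding",
                                 utr5_end = NA_integer_, cds_end = NA_integer_))
  expect_error(classify_annotated_cds(nc, "n"), "no annotated CDS")
})

test_that("uORF discovery is find_orfs restricted to the 5'-UTR", {
  txome <- make_test_txome()
  u <- discover_uorfs(txome, "tx1", orf_params(min_aa = 7))
  expect_equal(nrow(u), 1L)
  expect_equal(c(u$start, u$end, u$aa_length), c(0L, 27L, 8L))
  expect_true(all(u$end <= 30))

  # an ORF reading into the CDS is excluded: ATG near the UTR end, stop inside CDS
  seqs <- c(z = paste0(strrep("C", 6), "ATG", strrep("GGG", 10),
                       "ATG", strrep("CAC", 40), "TAA", strrep("C", 21)))
  info <- data.frame(transcript_id = "z", gene_id = "g", biotype = "coding",
                     utr5_end = 39L, cds_end = 39L + 126L)
  tz <- transcriptome(seqs, info)
  expect_equal(nrow(discover_uorfs(tz, "z", orf_params(min_aa = 5))), 0L)

  # composition oracle over random transcripts
  set.seed(33)
  for (i in 1:50) {
    u5 <- random_sequence(150)
    cds <- paste0("ATG", strrep("GCC", 30), "TGA")
    s <- c(paste0(u5, cds))
    names(s) <- "t"
    tr <- transcriptome(s, data.frame(transcript_id = "t", gene_id = "g",
                                      biotype = "coding", utr5_end = 150L,
                                      cds_end = 150L + nchar(cds)))
    got <- discover_uorfs(tr, "t", orf_params(min_aa = 4))
    want <- oracle_find_orfs(u5, min_aa = 4)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("ncORF discovery numbers features 5' to 3' and rejects coding input", {
  txome <- make_test_txome()
  orf1 <- paste0("ATG", strrep("AAC", 12), "TAA")
  orf2 <- paste0("ATG", strrep("GAC", 15), "TGA")
  s <- c(nc = paste0(strrep("C", 9), orf1, strrep("C", 12), orf2, strrep("C", 7)))
  tn <- transcriptome(s, data.frame(transcript_id = "nc", gene_id = "g",
                                    biotype = "noncoding",
                                    utr5_end = NA_integer_, cds_end = NA_integer_))
  got <- discover_ncorfs(tn, "nc", orf_params(min_aa = 11))
  expect_equal(got$feature_id, c("nc_ORF1", "nc_ORF2"))
  expect_true(got$start[1] < got$start[2])

  all_a <- transcriptome(c(x = strrep("A", 200)),
                         data.frame(transcript_id = "x", gene_id = "g",
                                    biotype = "noncoding",
                                    utr5_end = NA_integer_, cds_end = NA_integer_))
  expect_equal(nrow(discover_ncorfs(all_a, "x")), 0L)
  expect_error(discover_ncorfs(txome, "tx1"), "expected noncoding")
})

test_that("discovered uORFs and ncORFs never overlap the annotated CDS", {
  set.seed(44)
  for (i in 1:20) {
    cfg <- tiny_config(seed = 500 + i)
    sim <- simulate_transcriptome(cfg)
    feats <- discover_features(sim$txome)
    for (tx in unique(feats$transcript_id)) {
      reg <- tx_regions(sim$txome, tx)
      if (is.null(reg$cds)) next
      sub <- feats[feats$transcript_id == tx & feats$category %in% c("uorf", "ncorf"), ]
      if (nrow(sub)) {
        expect_true(all(sub$end <= reg$cds[1] | sub$start >= reg$cds[2]))
      }
    }
  }
})

test_that("uORF masking is exact interval subtraction", {
  seqs <- c(t = strrep("A", 200))
  txome <- transcriptome(seqs, data.frame(transcript_id = "t", gene_id = "g",
                                          biotype = "coding", utr5_end = 100L,
                                          cds_end = 160L))
  mk <- function(s, e) data.frame(feature_id = "u", transcript_id = "t",
                                  start = s, end = e, category = "uorf",
                                  aa_length = 1L)
  expect_equal(mask_uorfs_from_utr5(txome, "t", mk(10L, 43L)),
               data.frame(start = c(0L, 43L), end = c(10L, 100L)))
  none <- mask_uorfs_from_utr5(txome, "t", mk(10L, 43L)[0, ])
  expect_equal(none, data.frame(start = 0L, end = 100L))
  overlapping <- rbind(mk(10L, 43L), mk(40L, 76L))
  expect_equal(mask_uorfs_from_utr5(txome, "t", overlapping),
               data.frame(start = c(0L, 76L), end = c(10L, 100L)))
  expect_error(mask_uorfs_from_utr5(txome, "t", mk(90L, 123L)),
               "outside the 5'-UTR")

  # mask length + uORF union length == UTR length on random layouts
  set.seed(55)
  for (i in 1:50) {
    k <- sample(0:4, 1)
    st <- sort(sample(0:90, k))
    en <- pmin(st + sample(6:30, max(k, 1), replace = TRUE)[seq_len(k)], 100L)
    uorfs <- if (k) mk(st, en) else mk(10L, 43L)[0, ]
    masks <- mask_uorfs_from_utr5(txome, "t", uorfs)
    union_len <- if (k) sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = st + 1L, end = en)))) else 0L
    expect_equal(sum(masks$end - masks$start) + union_len, 100L)
  }
})

test_that("ORF features export to BED and TSV with peptides", {
  txome <- make_test_txome()
  feats <- discover_features(txome, orf_params(min_aa = 7))
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  out <- write_orf_features(txome, feats, bed, tsv)
  expect_true(file.exists(bed) && file.exists(tsv))
  cds1 <- out[out$feature_id == "tx1_CDS", ]
  expect_equal(cds1$peptide, paste0("M", strrep("E", 18)))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(feats))
})
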