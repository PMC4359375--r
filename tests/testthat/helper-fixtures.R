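# Small hand-built transcriptome used across unit tests:
#   tx1 coding  120 nt: utr5 [0,30), cds [30,90) (19 aa), utr3 [90,120)
#     with a uORF ATG + 7 codons + TAA at utr5 [0,27)
#   tx2 coding  180 nt: no utr5, cds [0,120) (39 aa), utr3 [120,180)
#   nc1 noncoding 100 nt: one ORF at [10,55) (ATG + 13 codons + stop)
make_test_txome <- function() {
  uorf <- paste0("ATG", strrep("GCA", 7), "TAA")          # 27 nt
  utr5_1 <- paste0(uorf, "CCC")                            # 30 nt, no other ATG
  cds1 <- paste0("ATG", strrep("GAA", 18), "TGA")          # 60 nt
  utr3_1 <- strrep("C", 30)
  cds2 <- paste0("ATG", strrep("CAT", 38), "TAG")          # 120 nt
  utr3_2 <- strrep("T", 60)
  nc_orf <- paste0("ATG", strrep("CCA", 13), "TAA")        # 45 nt
  nc1 <- paste0(strrep("C", 10), nc_orf, strrep("C", 45))  # 100 nt
  transcriptome(
    sequence = c(tx1 = paste0(utr5_1, cds1, utr3_1),
                 tx2 = paste0(cds2, utr3_2),
                 nc1 = nc1),
    info = data.frame(
      transcript_id = c("tx1", "tx2", "nc1"),
      gene_id = c("g1", "g2", "g3"),
      biotype = c("coding", "coding", "noncoding"),
      utr5_end = c(30L, 0L, NA),
      cds_end = c(90L, 120L, NA)
    )
  )
}

feature_row <- function(transcript_id, start, end, feature_id = "f1") {
  data.frame(feature_id = feature_id, transcript_id = transcript_id,
             start = as.integer(start), end = as.integer(end))
}

# scaled-down simulation config for fast unit tests
tiny_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_canonical = 20L, n_smorf = 15L, n_ncrna = 5L,
                   library_size_fp = 2e4, library_size_mrna = 2e4,
                   intergenic_n = 100L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
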