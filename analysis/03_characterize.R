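#!/usr/bin/env Rscript
# Stage 3: characterize called ORFs by phasing, conservation and amino-acid
# composition, and check replicate reproducibility.
#
# Reads the simulated experiment and the stage-2 calls; reports triplet
# phasing of signal vs UTR background, flags conserved features against the
# 90th percentile of intergenic conservation, tabulates amino-acid
# composition of translated smORFs against the random expectation from
# nucleotide composition, and computes the R^2 of footprint densities
# between two replicate library draws.

library(polyribo)

sim_dir <- file.path("results", "sim")
pipe_dir <- file.path("results", "pipeline")
out_dir <- file.path("results", "characterization")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

txome <- load_transcripts(file.path(sim_dir, "transcripts.fa"),
                          file.path(sim_dir, "transcripts.tsv"))
fp <- read_alignments_bed(file.path(sim_dir, "fp_small_polysome.bed"))
mrna <- read_alignments_bed(file.path(sim_dir, "mrna_fragments.bed"))
blocks <- read_conservation_bed(file.path(sim_dir, "conservation.bed"))
truth <- utils::read.delim(file.path(sim_dir, "truth_orfs.tsv"))
calls <- utils::read.delim(file.path(pipe_dir, "calls_small_polysome.tsv"),
                           comment.char = "#")

features <- discover_features(txome)
translated_ids <- calls$feature_id[calls$translated]

## triplet phasing: signal ORFs vs 3'-UTR background
orf_feats <- features[features$feature_id %in% translated_ids &
                        features$category %in%
                          c("canonical_cds", "smorf_cds", "uorf", "ncorf"), ]
utr3_feats <- features[features$category == "utr3_background", ]
ph_sig <- pooled_frame_distribution(orf_feats, fp)
ph_bg <- pooled_frame_distribution(utr3_feats, fp)
cat(sprintf("frame fractions, translated ORFs: %.3f / %.3f / %.3f (n = %d P-sites)\n",
            ph_sig$fractions[1], ph_sig$fractions[2], ph_sig$fractions[3],
            ph_sig$total))
cat(sprintf("frame fractions, 3'-UTR background: %.3f / %.3f / %.3f (n = %d)\n",
            ph_bg$fractions[1], ph_bg$fractions[2], ph_bg$fractions[3],
            ph_bg$total))
utils::write.table(
  data.frame(set = c("translated_orfs", "utr3_background"),
             rbind(ph_sig$fractions, ph_bg$fractions)),
  file.path(out_dir, "frame_fractions.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

## conservation: intergenic 90th percentile cut-off, per-category mean scores
# the simulator's intergenic sample is regenerated from the same seed
cfg <- sim_config(seed = seed)
sim <- simulate_transcriptome(cfg)
cons <- simulate_conservation(sim, seed = seed + 5L)
cutoff <- conservation_threshold(cons$intergenic_scores)
scores <- vapply(seq_len(nrow(features)), function(i)
  mean_conservation(features[i, ], blocks), numeric(1))
cons_tab <- data.frame(feature_id = features$feature_id,
                       category = features$category,
                       mean_score = scores,
                       conserved = flag_conserved(scores, cutoff),
                       translated = features$feature_id %in% translated_ids)
utils::write.table(cons_tab, file.path(out_dir, "conservation_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nintergenic conservation cut-off (90th pct): %.3f\n", cutoff))
tsm <- cons_tab$category == "smorf_cds" & cons_tab$translated
cat(sprintf("translated smORFs above cut-off: %.0f%% (median score %.2f, n = %d)\n",
            100 * mean(cons_tab$conserved[tsm]),
            stats::median(cons_tab$mean_score[tsm]), sum(tsm)))

## amino-acid composition vs the random expectation
nt_freq <- nucleotide_frequencies(txome$sequence)
pep <- write_orf_features(txome, features)
pick <- function(sel) pep$peptide[sel & !is.na(pep$peptide)]
sets <- list(
  all_cds = pick(pep$category %in% c("canonical_cds", "smorf_cds")),
  all_smorfs = pick(pep$category == "smorf_cds"),
  translated_smorfs = pick(pep$category == "smorf_cds" &
                             pep$feature_id %in% translated_ids))
comp <- composition_table(sets, nt_freq)
utils::write.table(comp, file.path(out_dir, "aa_composition.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\namino-acid composition (top enrichments of translated smORFs vs random):\n")
ord <- order(comp$translated_smorfs_vs_random, decreasing = TRUE)
print(utils::head(comp[ord, c("aa", "random_expected", "translated_smorfs",
                              "translated_smorfs_vs_random")], 5),
      row.names = FALSE)

## replicate reproducibility: an independent library draw from the same truth
loading <- simulate_polysome_loading(sim, seed = seed + 1L)
fp_rep <- simulate_footprints(sim, loading, "small_polysome", seed = seed + 7L)
m1 <- compute_feature_metrics(features, fp, mrna, txome, seed = seed + 6L)
m2 <- compute_feature_metrics(features, fp_rep, mrna, txome, seed = seed + 6L)
expressed <- m1$fp_count + m2$fp_count > 0
r2 <- replicate_correlation(m1[expressed, ], m2[expressed, ])
cat(sprintf("\nreplicate footprint-density R^2 over %d detected features: %.3f\n",
            sum(expressed), r2))

cat("\noutputs in", out_dir, "\n")
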