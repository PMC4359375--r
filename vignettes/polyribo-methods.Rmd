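---
title: "Calling smORF translation from polysome-fractionated ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling smORF translation from polysome-fractionated ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Small open reading frames (smORFs, at most 100 amino acids, hence at most
303 nt including the stop codon) are systematically under-annotated and hard
to validate: their short length gives them weak conservation signatures and
few peptides for proteomics. Ribosome profiling detects translation directly,
but on whole-cell lysate the signal is dominated by long, heavily loaded
mRNAs. Poly-Ribo-Seq sharpens the assay by footprinting sucrose-gradient
polysome fractions separately. The leverage comes from a packing argument: at
a density of one ribosome every 80 nt, and one at the start codon, a maximal
smORF can carry at most

    capacity(L) = 1 + ceiling(L / 80)  =  5 ribosomes for L = 303 nt,

so mRNAs whose only translated ORF is a smORF are confined to small polysomes
(2-6 ribosomes); large polysomes (7 or more) contain only long-ORF mRNAs.
Footprinting the small-polysome fraction therefore enriches actively
translated smORF mRNAs. `ribosome_capacity()` implements this convention;
a `strict_packing` mode (`1 + floor((L - footprint)/80)`, giving 4 for the
same smORF) is provided because tighter packing has been observed and the
additive convention is deliberately the more permissive of the two.

`polyribo` implements the downstream computational analysis as a tested
package: ORF discovery and classification, footprint metrics, background
thresholding, translation calls, and sequence characterization, plus a
synthetic-data generator with known ground truth so every stage is
exercisable offline.

## Coordinates and containers

All coordinates are 0-based half-open in transcript space; transcripts are
stored sense-strand, so strand handling ends at ingestion (GTF import
converts from 1-based closed at the boundary). Alignments are plain tables
(`transcript_id`, 5'-end `start`, `length`, `multiplicity`); BED6 is the
on-disk form via `rtracklayer`, with the score column carrying the
collapsed-duplicate multiplicity. Whether duplicates are collapsed is the
caller's choice — the multiplicity field supports both conventions.

## ORF discovery

`find_orfs()` scans all three frames for AUG codons followed by the first
in-frame stop, keeping peptides of at least `min_aa` (default 11, i.e.
"longer than 10 aa"; the smallest uORF we expect to call is 11 aa). Codons
containing `N` never match a start or stop — a conservative choice so that
ambiguous sequence cannot seed a call. Nested starts sharing a stop are
collapsed to the 5'-most AUG (`longest_per_stop`), mirroring typical
ORF-finder output; `all_starts` mode retains every start for sensitivity
studies. uORFs must be fully contained in the 5'-UTR, stop codon included:
an AUG whose ORF reads into the CDS is not a uORF here, which keeps uORF
metrics independent of CDS footprint signal (the upstream annotation is
silent on this; containment is the interpretation that keeps the metric
clean). For UTR occupancy analyses the 5'-UTR is masked: uORF intervals are
subtracted (`mask_uorfs_from_utr5()`) and the remaining `utr5_mask`
intervals are scored as their own features.

## Footprint metrics

Two deliberately different read-assignment rules coexist:

* **Counts** (`feature_read_count()`) use a single anchor point per read —
  the P-site (5' end + 12 nt for 28-29 nt reads, +13 for 30-31, +14 for 32)
  where the length is in the offset map, the read midpoint otherwise and for
  mRNA fragments — so adjacent features (UTR vs CDS) never double-count a
  read. Anchors use half-open boundaries: an anchor at `feature end` is
  outside.
* **Coverage** (`coverage_fraction()`) uses full read extents: the fraction
  of feature bases under at least one read. This is what makes the dwarf
  smORF arithmetic come out right — a single internal 32-nt footprint on a
  57-nt ORF yields 32/57 = 0.56.

Metrics consume gel-purification lengths 28-34 nt; framing consumes only
28-32 nt, the lengths with calibrated P-site offsets. RPKM is
`count / (L/1000) / (N/1e6)` with `N` the total retained transcript-aligned
reads of the experiment (whether the original denominator counted reads
outside annotated transcripts is unknowable from the publication; ours is a
declared convention). `metagene_composite()` sums read 5'-end counts at
offsets relative to start/stop codons; window defaults (-50,+100) and
(-100,+50) were chosen to display the boundary drop and are configurable.

## Translational efficiency and the expression gate

TE = footprint RPKM / mRNA RPKM, computed only for features whose mRNA
expression is significant against a randomized background: the observed mRNA
count is compared with `n_samples` length-matched intervals placed uniformly
over the concatenated transcript space, with the add-one empirical p-value
`(1 + #{null >= obs}) / (n_samples + 1)` and gate p < 0.01. One caveat
matters at desk scale: the original test randomized against *genomic*
background, which is mostly untranscribed, so expressed features pass
easily. Over transcript space the null intervals are as expressed as the
features, and the p-value becomes essentially a density rank — only the
densest ~1% of the transcriptome can pass. The gate is therefore
conservative here. Two consequences are handled explicitly: TE medians are
computed over the (few) gated features, with undefined TEs excluded rather
than zeroed; and the threshold background (next section) falls back to an
mRNA-presence gate when the strict gate leaves fewer than 20 UTRs, because a
90th percentile over a handful of points is not a cut-off worth trusting.

## Background thresholds and calling

The 3'-UTRs of transcribed canonical (>100 aa) mRNAs from the small-polysome
fraction act as the background: sequence that is present and polysome-bound
but not translated. `derive_thresholds()` sets the RPKM and coverage
cut-offs at their 90th percentiles. Two corrections ride on top:

1. the coverage cut-off is floored at 0.57, because a dwarf smORF under
   20 aa holding a single ribosome can already appear 0.56 covered, and
2. a feature needs at least 5 reads in a single experiment, so RPKM cannot
   be inflated by one or two reads on a very short feature.

`call_translation()` requires all three filters, with inclusive ("at least")
boundaries, making the call monotone in every metric.
`default_thresholds()` ships the published cut-offs (11.8 RPKM, 0.57
coverage, 5 reads) for use when no background can be derived. All
percentile steps — RPKM, coverage, and the conservation cut-off below —
share one quantile implementation, `quantile_linear()`, linear interpolation
between order statistics. Calls from multiple experiments combine by union
with per-experiment provenance (`combine_calls()`).

## Conservation and composition

`mean_conservation()` scores a feature as the overlap-length-weighted mean
of non-overlapping scored blocks; bases covered by no block contribute 0
(conservative; an `exclude` mode averages covered bases only). The
conserved/unconserved cut-off is the 90th percentile of intergenic feature
scores — by construction ~10% of intergenic features exceed it, which is the
sense in which the cut-off corresponds to a 10% false-discovery rate.
Blocks may be supplied directly in transcript space or any single coordinate
space shared with the features; there is no liftover support.

`random_expected_frequencies()` gives the null amino-acid usage implied by
nucleotide composition: codon probability is the product of its three
nucleotide frequencies, synonymous codons are summed, and the 61 sense
codons renormalized (stop codons excluded — the source is silent on stop
handling; renormalization is the cleanest choice). Observed composition
pools residues across peptides; `composition_table()` reports both raw
frequencies and ratios to random.

## The synthetic experiment

`sim_config()` fixes the study conditions; its defaults are the conditions
under which the pipeline is validated: 300 canonical genes (150-500 aa), 150
smORF genes (11-100 aa), 50 ncRNAs carrying 1-3 AUG ORFs (30% translated),
40% of 5'-UTRs holding one uORF (20% translated), 80% of annotated coding
genes translated, footprint libraries of 2e5 reads per fraction and 2e5 mRNA
fragments, frame fidelity 0.85, and 80-nt ribosome spacing.

The generative model: each transcript spawns
`Poisson(20 x abundance)` mRNA copies (abundance lognormal, sdlog 0.5);
copies of transcripts whose main ORF is translated load
`min(capacity, 1 + Poisson(rate))` ribosomes (rate lognormal, meanlog
log 3, sdlog 0.4 — the loading law is a modelling choice, nothing in the
source constrains it); untranslated copies carry 0-1 ribosomes. Copies are
labelled sub-polysomal (<= 1), small-polysome (2-6) or large-polysome
(>= 7), and each fraction's library is drawn multinomially over emission
sources: translated main ORFs emit proportionally to their copies' summed
ribosome counts (tying fraction identity to signal strength), secondary
translated ORFs at their own per-copy rate, and UTRs/ncRNA background at
2e-4 reads per nt per copy — with a 3x multiplier on 5'-UTRs, reflecting
scanning-ribosome occupancy, which is also what gives the expected median-TE
ordering CDS > masked 5'-UTR > 3'-UTR. Signal P-sites sit at codon starts
with probability 0.85, otherwise jittered +/-1 nt (empirical phasing leaks
into the adjacent frames rather than uniformly). Signal reads may overhang
an ORF's start codon (as real initiating footprints do) but never its 3'
end, so with background off a downstream UTR is exactly clean. Conservation
blocks tile each transcript (40-120 nt); blocks over translated ORFs draw
Beta(8, 4.12) scores (mean 0.66), all others and the intergenic sample draw
Beta(2, 4.43) (90th percentile 0.55).

Two simplifications to know about. Polysome loading follows the *dominant*
translated ORF per transcript; real fractions mix by total ribosome load
across all ORFs, so multi-ORF transcripts are cleaner here than in reality.
And UTR/ncRNA background sequence is scrubbed of AUG triplets outside
embedded ORFs, so the uORF/ncORF census is exactly the configured one;
off-frame AUGs inside embedded ORFs survive, so discovery can legitimately
report nested ORFs beyond the ground truth (recovery is asserted by
coordinates, in `all_starts` mode, because `longest_per_stop` deliberately
collapses a truth ORF nested in a longer same-stop ORF). The generator also
omits sequencing error, rRNA contamination and coverage biases; passing
tests show the analysis recovers its own generative truth, not that it is
robust to artefacts of real libraries.

## Numerical and edge-case conventions

* One seed governs the whole experiment; stage functions accept explicit
  seeds and the bundle derives them as fixed offsets from the config seed.
* Empty footprint libraries produce zero metrics with a warning (not an
  error), so background-only experiments tabulate; an empty threshold
  background falls back to `default_thresholds()` with a warning.
* `frame_distribution()` with zero included reads returns total 0 with `NA`
  fractions — an undefined result, distinct from an error.
* Degenerate nucleotide compositions (some amino acids impossible) are
  permitted; the expectation renormalizes over what remains.
* Ties in empirical p-values are counted against the feature
  (`null >= observed`), the conservative direction.

## Problem sizes

The test suite validates operations against brute-force oracles on 100+
random fixtures each, and runs the full default-size experiment end to end:
truth recovery over five seeds (~25 s per seed on one core), phasing on a
deep 15-gene simulation, and the metagene/TE shape checks on a 150-gene
simulation. `scripts/acceptance.R` re-runs the default experiment from
scratch at a caller-chosen seed in about 20 s.

## Limitations

Genome-coordinate ORF calling across splice junctions, non-AUG starts,
mismatch/unique-mapping logic, isoform deconvolution of shared reads, and
statistical comparison of TE between fractions are out of scope. The
expression gate's transcript-space null is conservative (see above); with
real genome-aligned data the original genomic null would be the better
analogue.
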