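Package: polyribo
Title: Polysome-Fractionated Ribosome Profiling Analysis of Small ORF Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of polysome-fractionated ribosome profiling
    (Poly-Ribo-Seq) for calling translation of small open reading frames
    (smORFs), upstream ORFs and ORFs in non-coding RNAs. Discovers and
    classifies AUG-initiated ORFs on a transcriptome, computes footprint
    metrics (RPKM, coverage, P-site framing, metagene composites,
    translational efficiency), derives background cut-offs from canonical
    3'-UTR signal, calls translated features, and characterizes them by
    conservation and amino-acid composition. Includes a simulator of
    polysome loading, footprints, mRNA fragments and conservation tracks
    with known ground truth, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
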