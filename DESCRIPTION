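Package: totikit
Title: Totivirus Genome Annotation, Frameshift Element Detection, and
    Small-RNA Profiling
Version: 0.1.0
Authors@R:
    person("Totikit", "Developers", email = "totikit@example.org",
           role = c("aut", "cre"))
Description: Tools for desk-scale characterization of totivirus (dsRNA
    mycovirus) genomes: open reading frame discovery and genome layout
    annotation (UTRs, intergenic region, GC content, protein masses),
    detection of -1 programmed ribosomal frameshift elements (canonical
    slippery heptamer, spacer, and H-type pseudoknot with a simple
    additive energy model), derivation of the CP-RdRp fusion protein,
    conserved-residue anchoring by pairwise global alignment (the
    cap-snatching histidine of the capsid protein and the GDD motif of
    the RNA-dependent RNA polymerase), and mismatch-tolerant mapping of
    small-RNA reads with per-length mismatch-class profiling
    (usRNA/siRNA classification). A synthetic-data generator plants
    fully known genome structure and read populations so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
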