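---
title: "Characterizing totivirus genomes with totikit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing totivirus genomes with totikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(totikit)
```

## The analysis this package implements

Totiviruses are non-segmented dsRNA viruses (~4.6–7.0 kbp) whose
genomes carry two long ORFs: a 5' capsid protein (CP) gene and a 3'
RNA-dependent RNA polymerase (RdRp) gene, usually expressed as a single
CP–RdRp fusion protein via a −1 programmed ribosomal frameshift (PRF).
Characterizing a newly assembled totivirus genome is a stereotyped desk
analysis:

1. find the two long ORFs and derive the genome layout — 5' UTR, ORF1,
   intergenic region (IR), ORF2, 3' UTR — plus GC content and protein
   masses;
2. locate the −1 PRF element near the ORF1 stop: a slippery heptamer of
   the canonical form `XXXYYYZ` (three identical X, three identical
   Y ∈ {A,U}, Z ∈ {A,C,U}), a short spacer, and a downstream H-type
   pseudoknot;
3. derive the fusion protein implied by the slip;
4. anchor conserved residues (the cap-snatching histidine of yeast
   totivirus CPs, the RdRp motifs including GDD) against references;
5. profile virus-derived small RNAs: map reads against the viral and
   host genomes tolerating at most one mismatch, tabulate counts per
   read length split by mismatch class, and classify reads as usRNA
   (13–19 nt) or siRNA (20–24 nt).

totikit implements each stage as a tested, deterministic operation and
adds a synthetic-data generator that plants all of this structure with
known coordinates, so the full pipeline can be exercised and verified
without any downloads.

## Coordinate, alphabet and frame conventions

All coordinates are 1-based inclusive (identical to GFF3, so emission
involves no conversion). The internal alphabet is RNA; DNA input is
converted (T→U) on read. Ambiguity codes are rejected by default
because a 4.5 kb genome assembly should be unambiguous — silent masking
tends to hide upstream assembly problems; `allow_ambiguity = TRUE`
maps them to `N`, which never base-pairs and always counts as a
mismatch in read mapping. Frame *f* ∈ {1,2,3} means codons start at
positions *p* with (*p* − *f*) mod 3 = 0. An ORF runs from its AUG
through its stop codon; reported protein lengths exclude the stop, so
`protein_length = nt_length/3 − 1` holds for every reported ORF.

## ORF discovery and layout annotation

`find_orfs()` scans the requested frames for maximal AUG-initiated,
stop-terminated readings of at least `min_aa` codons, suppressing
nested internal AUGs (longest-per-stop rule) — this matches how a
single CP or RdRp ORF per region is conventionally reported. Defaults:
`min_aa = 100` (excludes spurious short ORFs at 4.5 kb scale while
retaining both long ORFs) and plus-strand-only scanning (totivirus
coding is single-stranded; `strand_policy = "both"` is available).
`select_orf_pair()` picks the two longest non-overlapping ORFs in
distinct frames; `annotate_genome()` derives the UTR/IR intervals,
which must tile the genome exactly when the ORFs are disjoint — an
invariant asserted in the tests.

Protein masses use *average* (not monoisotopic) residue masses plus one
water, the convention behind "estimated molecular mass" figures for
viral proteins; GC content is reported half-up at one decimal.

## The −1 PRF element

`scan_slippery()` matches the canonical heptamer grammar within
`max_upstream` (default 200 nt; characterized sites sit ~110–150 nt
upstream of the ORF1 end) and, by default, keeps only heptamers whose
3' end falls on an ORF1 codon boundary — both characterized totivirus
heptamers satisfy this, and the fusion arithmetic requires it. The
filter can be relaxed (`require_codon_boundary = FALSE`).

`find_pseudoknots()` searches **downstream** of the heptamer. (Some
prose describes the pseudoknot as "preceding" the slippery site, but
every mapped totivirus element and the broader −1 PRF literature place
it downstream; the package treats the prose as an erratum.) It
exhaustively enumerates crossing stem pairs in the layout
`S1a–L1–S2a–L2–S1b–L3–S2b` subject to `pk_params()` bounds (stems 3–10
bp, loops L1 ∈ [1,10], L2 ∈ [0,20], L3 ∈ [1,40], span ≤ 80 nt, window
≤ 120 nt), allowing Watson–Crick and G·U pairs in stems.

Because the tool behind published "estimated free energy" figures is
unstated, candidates are ranked by a deliberately simple additive
surrogate:

* per pair: GC −3.0, AU −2.0, GU −1.0 kcal/mol;
* +0.2 kcal/mol per unpaired loop nucleotide;
* +7.0 kcal/mol pseudoknot initiation penalty.

This model is reproducible, independently re-summable (the test suite
re-derives every reported energy from the pair lists), and sufficient
to rank candidates; it is *not* comparable to Turner-model free
energies, and published EFE values are deliberately not reproduced.
Ties are broken by smaller span, then 5'-most start, making the search
deterministic. `assemble_prf()` accepts spacers in [1, 30] nt
(characterized spacers: 4 and 27 nt).

`fusion_protein()` implements the −1 slip: the ribosome re-reads the
final heptamer base, so translation covers ORF1 codons through the
heptamer 3' end, then resumes *at that same position* in the −1 frame
and runs to the codon before the ORF2 stop. Preconditions (heptamer end
on the ORF1 codon grid; post-shift frame equal to ORF2's frame) are
checked and reported by name, as is the position of any internal stop.

## Motif anchoring

Rather than re-implementing progressive multiple alignment, conserved
residues are anchored by pairwise global alignment (Gotoh affine-gap
Needleman–Wunsch; BLOSUM62, gap open 11, extend 1, a gap of length L
costing 11 + L) with deterministic traceback (diagonal, then up, then
left). `anchor_residue()` maps a reference position through the
alignment and reports whether the query residue matches; positions
falling in a gap are reported unmatched with the nearest aligned
residue flagged. `scan_gdd()` finds every GDD tripeptide and flags the
hit anchored inside the reference motif-VI region as canonical.

The packaged references are **synthetic stand-ins**: deposited yeast
totivirus proteins are not redistributed with the package, so
deterministic surrogate sequences carrying the documented landmarks
(CP histidine at position 154; RdRp motif-VI GDD) are shipped instead,
labelled synthetic in both filename and header. They exercise the
anchoring machinery fully — e.g. prepending k residues to a query
shifts the anchored position by exactly k, which is how the
position-158 variant of the histidine arises in a CP with a 4-residue
N-terminal extension — but positional claims about the historical
proteins require the real references.

## Small-RNA profiling

`map_read()` is an exhaustive Hamming-distance matcher: every offset on
both strands is scanned, a read maps iff some placement has ≤ `max_mm`
mismatches (default 1), and the minimum-mismatch placement is reported
with ties broken plus-strand-first, then smallest position. Matching is
exact Hamming — no indels and no G·U tolerance; reverse complementation
uses the RNA alphabet. A read is counted once per target it maps to.

`build_profile()` discards reads shorter than 10 nt (the smallest
published table row), pools reads longer than 30 nt into a ">30" bin,
and tabulates per-length totals split into perfect-match and
one-mismatch classes; `total = perfect + one_mismatch` holds row-wise
by construction and is asserted in tests. `classify_lengths()`
aggregates into usRNA (13–19 nt), siRNA (20–24 nt) and other, and
emits log-scale histogram data.

`fraction_perfect()` reports 100 × perfect/total with half-up rounding
at two decimals. One published value cannot be reconciled with any
single 2-decimal convention: 2097/94044 = 2.2298% is printed as 2.23%
(rounding), while 841/111335 = 0.7554% is printed as 0.75% (truncation;
half-up gives 0.76%). The package sticks to half-up rounding and the
acceptance suite compares that value at printed precision ±1 unit in
the last digit.

## The synthetic data generator: what it emulates, and what not

`make_genome()` defaults *are* the characterized GcTV2-class layout:
4592 nt; UTR5/IR/UTR3 = 29/326/37 nt; ORF1 of 2043 nt in frame 3; ORF2
implied (2157 nt, frame 2); heptamer GGGUUUA ending 108 nt upstream of
the ORF1 end on a codon boundary; spacer 4 nt; a 55 nt pseudoknot with
6 + 5 bp GC stems and loops 2/11/20; target GC 0.455; a His codon at
ORF1 position 154 and a GDD at ORF2 position 450.
`genome_params_gctv4()` gives the second characterized layout (4530 nt,
5/20/35 nt segments, UUUUUUA, spacer 27, 21 nt pseudoknot with 4 + 3 bp
stems). Where the source states no value (pseudoknot stem/loop split
within the published span, landmark positions inside ORF2), a single
realistic choice was made once and kept.

The generator is *constructive*, not merely rejective:

* ORFs are built from non-stop codons with planted AUG/stop ends;
* the −1 fusion frame from the heptamer 3' end to the ORF2 start is
  filled left-to-right so that no codon of that frame is a stop or an
  AUG — a stop would truncate the fusion protein, and an AUG would
  open a competing long ORF sharing ORF2's stop, breaking
  longest-per-stop recovery;
* a stop codon is planted in the −1 frame immediately 5' of the
  heptamer, so no upstream AUG can read through into ORF2's frame;
* pseudoknot stems are all-GC (GC-only sequence can never form a stop
  or AUG in any frame, and makes the planted structure the strongest in
  its window under the energy model), with A·A guard bases at the stem
  junctions so no enumerated helix can extend a planted stem and
  displace the planted span as the best-scoring candidate.

After construction the generator *proves* recovery — it runs the actual
annotation and PRF scan and resamples (up to 1000 times; typically 1–3
attempts) until the recovered coordinates equal the planted truth
exactly. The emitted `synthetic_truth` object is therefore a
certificate, which is what makes the 100-seed recovery suite a test of
the pipeline rather than of luck.

`make_srna_reads()` draws read lengths from the published viral
size-distribution shape (10–20 nt, heavily skewed short), plants 0 or 1
substitutions per read (perfect fraction defaulting to the published
2.23%), and re-draws any read whose planted mutation is shadowed by an
accidental perfect match elsewhere on its origin target — guaranteeing
that the planted mismatch count is the read's true minimal Hamming
distance, so profiler output can be compared to the truth read by read.

What the generator does **not** emulate: real fungal genome
composition (host background is i.i.d. at a target GC), quality-score-
correlated sequencing error, multi-locus repeat structure, and
realistic read-depth biases. A green recovery test therefore
establishes that the pipeline's logic is correct on genomes satisfying
the totivirus layout assumptions — not that it is robust to messy real
assemblies. Requested GC is a sampling target; planted coding and
structural constraints shift realized GC by a few points.

## Numerical and degenerate-input choices

* Percentages: half-up at 2 decimals (see above); GC at 1 decimal.
* Masses: average residue masses, 2 decimals, half-up.
* `find_pseudoknots()` refuses windows wider than 120 nt rather than
  silently scanning quadratically many candidates.
* Empty read sets yield all-zero profiles; an empty profile makes
  `fraction_perfect()` return `NA` with a warning rather than dividing
  by zero.
* Equal-energy pseudoknots: smaller span wins, then 5'-most start.
* `map_read` ties: plus strand, then smallest position.
* The pipeline validates its whole config (unknown keys rejected)
  before any stage runs; a stage failure is recorded in the report and
  downstream stages are skipped.

## Known limitations

* The pseudoknot energy model is a ranking surrogate; do not compare
  its values across packages or to experimental stabilities.
* Mapping is exhaustive-scan; it is meant for ≤10^5 reads against
  genome-scale targets of a few kb (the desk-scale contract), not for
  full sRNA libraries against a fungal genome.
* Motif anchoring is pairwise; clade assignment and phylogenetics are
  out of scope.
* Packaged references are synthetic; swap in real CP/RdRp references
  (same FASTA/TSV layout) for positional claims about real proteins.
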