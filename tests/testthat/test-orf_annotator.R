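# ORF discovery, layout arithmetic, translation, masses.

test_that("find_orfs handles the minimal and empty cases", {
  g <- genome_record("t", "AUGAAAUAA")
  orfs <- find_orfs(g, min_aa = 1)
  expect_length(orfs, 1L)
  expect_equal(orfs[[1]]$interval$start, 1L)
  expect_equal(orfs[[1]]$interval$end, 9L)
  expect_equal(orfs[[1]]$protein, "MK")

  expect_length(find_orfs(genome_record("t", "CCCCCCUAACCC"), min_aa = 1),
                0L)
})

test_that("find_orfs equals brute-force enumeration on random sequences", {
  set.seed(101)
  for (i in 1:50) {
    g <- genome_record(paste0("r", i), random_rna(300))
    got <- find_orfs(g, min_aa = 5)
    want <- oracle_find_orfs(g$sequence, min_aa = 5)
    expect_equal(length(got), nrow(want), info = paste("seq", i))
    if (length(got) > 0L) {
      expect_equal(vapply(got, function(o) o$interval$start, integer(1)),
                   want$start)
      expect_equal(vapply(got, function(o) o$interval$end, integer(1)),
                   want$end)
    }
  }
})

test_that("every reported ORF satisfies the protein-length identity", {
  set.seed(102)
  for (i in 1:20) {
    g <- genome_record("r", random_rna(800))
    for (o in find_orfs(g, min_aa = 3)) {
      expect_equal(o$nt_length %% 3L, 0L)
      expect_equal(o$protein_length, o$nt_length / 3L - 1L)
      expect_false(grepl("\\*", o$protein))
    }
  }
})

test_that("translation agrees with a codon-table lookup oracle", {
  expect_equal(translate_rna("AUGAAAUAA"), "MK")
  expect_error(translate_rna("AUGAXA"), "non-ACGU")
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("T", "U", names(code))
  set.seed(103)
  for (i in 1:30) {
    n_codons <- sample(1:50, 1)
    s <- random_rna(3 * n_codons)
    codons <- substring(s, seq(1, 3 * n_codons, 3), seq(3, 3 * n_codons, 3))
    aa <- code[codons]
    first_stop <- which(aa == "*")
    if (length(first_stop) > 0) aa <- aa[seq_len(first_stop[1] - 1)]
    expect_equal(translate_rna(s), paste(aa, collapse = ""))
  }
})

test_that("protein masses match manual summation of average masses", {
  # residue masses summed by hand from the standard average-mass table
  expect_equal(protein_mass("G", digits = 5), 0.07507, tolerance = 1e-6)
  met <- 131.1926; lys <- 128.1741; water <- 18.01528
  expect_equal(protein_mass("MK", digits = 5),
               round((met + lys + water) / 1000, 5), tolerance = 1e-6)
  expect_error(protein_mass("MKZ"), "unknown residue")
  expect_error(protein_mass(""), "empty")
})

test_that("published genome layouts reproduce the printed segment lengths", {
  # GcTV2-class: 4592 nt, ORF1 30-2072, ORF2 2399-4555
  sim <- make_genome(seed = 104)
  ann <- annotate(sim$genome)
  expect_equal(interval_length(ann$utr5), 29L)
  expect_equal(interval_length(ann$intergenic), 326L)
  expect_equal(interval_length(ann$utr3), 37L)
  expect_equal(ann$orf1$nt_length, 2043L)
  expect_equal(ann$orf1$protein_length, 680L)
  expect_equal(ann$orf2$nt_length, 2157L)
  expect_equal(ann$orf2$protein_length, 718L)

  # GcTV4-class: 4530 nt, ORF1 6-2102, ORF2 2123-4495
  sim4 <- make_genome(genome_params_gctv4(), seed = 105)
  ann4 <- annotate(sim4$genome)
  expect_equal(interval_length(ann4$utr5), 5L)
  expect_equal(interval_length(ann4$intergenic), 20L)
  expect_equal(interval_length(ann4$utr3), 35L)
  expect_equal(ann4$orf1$nt_length, 2097L)
  expect_equal(ann4$orf1$protein_length, 698L)
  expect_equal(ann4$orf2$nt_length, 2373L)
  expect_equal(ann4$orf2$protein_length, 790L)
})

test_that("annotation segments tile the genome exactly", {
  set.seed(106)
  for (seed in 1:5) {
    sim <- make_genome(seed = seed)
    ann <- annotate(sim$genome)
    total <- interval_length(ann$utr5) + ann$orf1$nt_length +
      interval_length(ann$intergenic) + ann$orf2$nt_length +
      interval_length(ann$utr3)
    expect_equal(total, ann$genome_length)
  }
})

test_that("ORFs tiling the whole genome leave no UTRs", {
  g <- genome_record("t", paste0(
    "AUG", strrep("GCU", 120), "UAA",          # ORF1: 1-366, frame 1
    "AUG", strrep("GCC", 120), "UAA"))         # ORF2: 367-732, frame 1
  # same frame: shift ORF2 by inserting one base is not possible while
  # tiling, so annotate_genome is called directly on the two ORFs
  o1 <- orf_annotation(g, 1, 366)
  o2 <- orf_annotation(g, 367, 732)
  ann <- annotate_genome(g, o1, o2)
  expect_null(ann$utr5)
  expect_null(ann$utr3)
  expect_null(ann$intergenic)
})

test_that("annotate_genome validates bounds and overlap", {
  g <- genome_record("t", paste0("AUG", strrep("GCU", 30), "UAA",
                                 "CC", "AUG", strrep("GAC", 30), "UAA"))
  o1 <- orf_annotation(g, 1, 96)
  o2 <- orf_annotation(g, 99, 194)
  expect_error(orf_annotation(g, 99, 200), "exceeds")
  expect_error(annotate_genome(g, o2, o1), "overlap")
  ann <- annotate_genome(g, o1, o2)
  expect_equal(interval_length(ann$intergenic), 2L)
})

test_that("GC content uses half-up rounding at one decimal", {
  expect_equal(gc_percent("GCGC"), 100)
  expect_equal(gc_percent("AUAU"), 0)
  expect_equal(gc_percent(strrep("GCAU", 10)), 50)
  # 5/11 = 45.4545... -> 45.5
  expect_equal(gc_percent(paste0(strrep("G", 5), strrep("A", 6))), 45.5)
})
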