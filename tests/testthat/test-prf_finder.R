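# Slippery heptamers, pseudoknots, PRF assembly, fusion proteins.

test_that("heptamer grammar accepts the published sites and rejects violations", {
  expect_true(is_slippery_heptamer("GGGUUUA"))   # GcTV2-class site
  expect_true(is_slippery_heptamer("UUUUUUA"))   # GcTV4-class site
  expect_false(is_slippery_heptamer("GGGUUUG"))  # Z = G
  expect_false(is_slippery_heptamer("GGAUUUA"))  # X triplet broken
  expect_false(is_slippery_heptamer("GGGCCCA"))  # Y not in {A,U}
  expect_false(is_slippery_heptamer("GGGUUU"))   # too short
})

test_that("scan_slippery equals a brute-force grammar scan on random sequence", {
  set.seed(201)
  for (rep in 1:5) {
    seq <- random_rna(2000)
    # plant a few canonical heptamers
    for (pos in c(300, 900, 1500)) {
      substr(seq, pos, pos + 6) <- "AAAUUUC"
    }
    g <- genome_record("r", paste0(substr(seq, 1, 1994), "UAA"))
    # treat the whole sequence as one ORF-like frame-1 window
    orf1 <- structure(
      list(interval = interval(1L, 1997L), frame = 1L),
      class = "orf_annotation")
    got <- scan_slippery(g, orf1, max_upstream = 1996L,
                         require_codon_boundary = FALSE)
    starts <- integer(0)
    for (s in 1:(1997 - 6)) {
      if (oracle_slippery(substr(g$sequence, s, s + 6))) {
        starts <- c(starts, s)
      }
    }
    expect_equal(vapply(got, function(x) x$interval$start, integer(1)),
                 starts)
  }
})

test_that("codon-boundary annotation and filtering are consistent", {
  sim <- make_genome(seed = 202)
  ann <- annotate(sim$genome)
  sites <- scan_slippery(sim$genome, ann$orf1)
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_equal(s$heptamer, "GGGUUUA")
  expect_equal(c(s$interval$start, s$interval$end), c(1958L, 1964L))
  expect_true(s$on_codon_boundary)
  expect_equal((s$interval$end - ann$orf1$interval$start + 1L) %% 3L, 0L)
  all_sites <- scan_slippery(sim$genome, ann$orf1,
                             require_codon_boundary = FALSE)
  expect_gte(length(all_sites), length(sites))
})

test_that("pk_energy reproduces hand-summed model energies", {
  # minimal legal pseudoknot: two 3-bp GC stems, loops 2/0/2
  #   S1a   L1  S2a  S1b   L3  S2b
  #   GGG   AA  GGG  CCC   AA  CCC
  g <- genome_record("pk", "GGGAAGGGCCCAACCC")
  pks <- find_pseudoknots(g, interval(1L, 16L),
                          pk_params(min_stem = 3L, max_stem = 3L,
                                    loop1 = c(1L, 5L), loop2 = c(0L, 5L),
                                    loop3 = c(1L, 5L), max_span = 20L))
  expect_gte(length(pks), 1L)
  top <- pks[[1]]
  expect_equal(top$span$start, 1L)
  expect_equal(top$span$end, 16L)
  expect_equal(unname(top$loop_lengths), c(2L, 0L, 2L))
  expect_equal(top$efe_kcal_mol, 6 * (-3.0) + 4 * 0.2 + 7.0)  # -10.2
  # adding one GC pair to a stem shifts the energy by exactly -3
  g2 <- genome_record("pk2", "GGGGAAGGGCCCCAACCC")
  pks2 <- find_pseudoknots(g2, interval(1L, 18L),
                           pk_params(min_stem = 3L, max_stem = 4L,
                                     loop1 = c(1L, 5L), loop2 = c(0L, 5L),
                                     loop3 = c(1L, 5L), max_span = 20L))
  expect_equal(pks2[[1]]$efe_kcal_mol, top$efe_kcal_mol - 3.0)
})

test_that("a poly-A window holds no pseudoknot and long windows error", {
  g <- genome_record("a", strrep("A", 200))
  expect_length(find_pseudoknots(g, interval(1L, 100L)), 0L)
  expect_error(find_pseudoknots(g, interval(1L, 130L)), "max_window")
})

test_that("reported energies agree with independent re-summation", {
  set.seed(203)
  n_checked <- 0L
  for (rep in 1:20) {
    g <- genome_record("r", random_rna(90))
    pks <- find_pseudoknots(g, interval(1L, 90L))
    for (pk in head(pks, 5)) {
      expect_equal(pk$efe_kcal_mol, oracle_pk_energy(pk, g$sequence))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("pseudoknot stems satisfy pairing and crossing invariants", {
  set.seed(204)
  for (rep in 1:10) {
    g <- genome_record("r", random_rna(80))
    for (pk in head(find_pseudoknots(g, interval(1L, 80L)), 10)) {
      chars <- strsplit(g$sequence, "")[[1]]
      for (stem in list(pk$stem1, pk$stem2)) {
        pairs <- paste0(chars[stem[, 1]], chars[stem[, 2]])
        expect_true(all(pairs %in% c("GC", "CG", "AU", "UA", "GU", "UG")))
      }
      # crossing: stem2's 5' half inside stem1's enclosed region,
      # 3' half beyond stem1's 3' end
      expect_true(all(pk$stem2[, 1] > max(pk$stem1[, 1])))
      expect_true(all(pk$stem2[, 1] < min(pk$stem1[, 2])))
      expect_true(all(pk$stem2[, 2] > max(pk$stem1[, 2])))
      # no position used twice
      pos <- c(pk$stem1, pk$stem2)
      expect_equal(anyDuplicated(pos), 0L)
    }
  }
})

test_that("find_pseudoknots is deterministic across calls", {
  g <- make_genome(seed = 205)$genome
  w <- interval(1965L, 2064L)
  a <- find_pseudoknots(g, w)
  b <- find_pseudoknots(g, w)
  expect_identical(lapply(a, function(p) p[c("stem1", "stem2", "span")]),
                   lapply(b, function(p) p[c("stem1", "stem2", "span")]))
})

test_that("assemble_prf applies the spacer arithmetic and bounds", {
  sim <- make_genome(seed = 206)
  ann <- annotate(sim$genome)
  scan <- prf_scan(sim$genome, ann$orf1, ann$orf2)
  expect_false(is.null(scan$best))
  best <- scan$best
  # printed GcTV2 geometry: heptamer ends 1964, pseudoknot starts 1969
  expect_equal(best$slippery$interval$end, 1964L)
  expect_equal(best$pseudoknot$span$start, 1969L)
  expect_equal(best$spacer_length, 4L)
  for (e in scan$elements) {
    expect_equal(e$spacer_length,
                 e$pseudoknot$span$start - e$slippery$interval$end - 1L)
    expect_gte(e$spacer_length, 1L)
    expect_lte(e$spacer_length, 30L)
  }
  # a pseudoknot adjacent to the heptamer (spacer 0) is excluded
  sites <- scan_slippery(sim$genome, ann$orf1)
  pk0 <- find_pseudoknots(sim$genome, interval(1965L, 2050L))
  adjacent <- Filter(function(p) p$span$start == 1965L, pk0)
  if (length(adjacent) > 0L) {
    expect_length(assemble_prf(sites[[1]], adjacent), 0L)
  }
})

test_that("GcTV4-class geometry yields the 27 nt spacer", {
  sim <- make_genome(genome_params_gctv4(), seed = 207)
  ann <- annotate(sim$genome)
  scan <- prf_scan(sim$genome, ann$orf1, ann$orf2)
  expect_equal(scan$best$slippery$heptamer, "UUUUUUA")
  expect_equal(scan$best$slippery$interval$end, 1949L)
  expect_equal(scan$best$pseudoknot$span$start, 1977L)
  expect_equal(scan$best$spacer_length, 27L)
})

test_that("fusion_protein implements the -1 slip on a hand-translated toy", {
  # ORF1 1-12 (AUG GGU UUA UAA), heptamer GGGUUUA at 3-9,
  # ORF2 12-20 (AUG GCC UAA) overlapping the ORF1 stop
  g <- genome_record("toy", "AUGGGUUUAUAAUGGCCUAAA")
  o1 <- orf_annotation(g, 1, 12)
  o2 <- orf_annotation(g, 12, 20)
  site <- scan_slippery(g, o1, max_upstream = 11L)[[1]]
  expect_equal(site$interval$end, 9L)
  fus <- fusion_protein(g, o1, site, o2)
  expect_equal(fus$pre_shift_codons, 3L)
  expect_equal(fus$post_shift_codons, 3L)
  # hand translation: AUG GGU UUA | AUA AUG GCC -> MGL + IMA
  expect_equal(fus$protein, "MGLIMA")
})

test_that("fusion_protein rejects inconsistent frame geometry", {
  g <- genome_record("toy", "AUGGGUUUAUAAUGGCCUAAA")
  o1 <- orf_annotation(g, 1, 12)
  o2 <- orf_annotation(g, 12, 20)
  bad_site <- structure(
    list(interval = interval(2L, 8L), heptamer = "NNNNNNN",
         x = "N", y = "N", z = "N", distance_to_orf1_stop = 4L,
         on_codon_boundary = FALSE),
    class = "slippery_site")
  expect_error(fusion_protein(g, o1, bad_site, o2), "codon boundary")
})

test_that("published fusion lengths derive from printed coordinates", {
  sim2 <- make_genome(seed = 208)
  ann2 <- annotate(sim2$genome)
  s2 <- scan_slippery(sim2$genome, ann2$orf1)[[1]]
  fus2 <- fusion_protein(sim2$genome, ann2$orf1, s2, ann2$orf2)
  expect_equal(fus2$pre_shift_codons, 645L)   # (1964 - 30 + 1) / 3
  expect_equal(fus2$post_shift_codons, 863L)  # (4552 - 1964 + 1) / 3
  expect_equal(fus2$protein_length, 1508L)

  sim4 <- make_genome(genome_params_gctv4(), seed = 209)
  ann4 <- annotate(sim4$genome)
  s4 <- scan_slippery(sim4$genome, ann4$orf1)[[1]]
  fus4 <- fusion_protein(sim4$genome, ann4$orf1, s4, ann4$orf2)
  expect_equal(fus4$pre_shift_codons, 648L)
  expect_equal(fus4$post_shift_codons, 848L)
  expect_equal(fus4$protein_length, 1496L)
})
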