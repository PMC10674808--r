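# Read mapping, length/mismatch profiling, classification.

test_that("map_read handles exact substrings and unmappable reads", {
  g <- genome_record("t", "AUGCAUGGCAUUACGGAUCGAUCG")
  r <- map_read("AUGGCAUU", g)
  expect_true(r$mapped)
  expect_equal(r$position, 5L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$strand, "+")

  r2 <- map_read(strrep("C", 20), genome_record("t2", strrep("A", 50)))
  expect_false(r2$mapped)
})

test_that("map_read agrees with the exhaustive Hamming oracle on 500 planted reads", {
  sim <- make_genome(seed = 501)
  rd <- make_srna_reads(sim$genome, n_reads = 500, perfect_fraction = 0.5,
                        seed = 502)
  agree <- 0L
  for (i in seq_len(500L)) {
    got <- map_read(rd$reads[i, ], sim$genome)
    want <- oracle_map(sim$genome$sequence, rd$reads$sequence[i])
    ok <- identical(got$mapped, want$mapped) &&
      identical(as.integer(got$mismatches), as.integer(want$mismatches)) &&
      identical(as.integer(got$position), as.integer(want$position)) &&
      (!got$mapped || identical(got$strand, want$strand))
    if (ok) agree <- agree + 1L
  }
  expect_equal(agree, 500L)
})

test_that("minus-strand placements and tie-breaks follow the contract", {
  set.seed(503)
  g <- genome_record("t", random_rna(300))
  # a read taken from the minus strand
  sub <- substr(g$sequence, 100, 119)
  mread <- revcomp_rna(sub)
  r <- map_read(mread, g)
  expect_true(r$mapped)
  expect_equal(r$strand, "-")
  expect_equal(r$position, 100L)
  # plus strand wins ties: palindromic-ish read planted on both strands
  g2 <- genome_record("t2", "AAAAUUUUGGGGAAAAUUUU")
  r2 <- map_read("AAAAUUUU", g2)
  expect_equal(r2$strand, "+")
  expect_equal(r2$position, 1L)
})

test_that("profiles conserve row sums and respect the length filter", {
  sim <- make_genome(seed = 504)
  rd <- make_srna_reads(sim$genome, n_reads = 2000,
                        perfect_fraction = 0.3, seed = 505)
  prof <- build_profile(rd$reads, sim$genome)[[1]]
  expect_true(all(prof$total == prof$perfect_match + prof$one_mismatch))
  expect_equal(sum(prof$total), 2000L)  # all planted reads map
  expect_equal(prof$length,
               c(as.character(10:30), ">30"))
  # reads shorter than 10 nt are dropped before mapping
  short <- srna_set(c("a", "b"), c("ACGUA", substr(sim$genome$sequence, 1, 15)))
  prof2 <- build_profile(short, sim$genome)[[1]]
  expect_equal(sum(prof2$total), 1L)
})

test_that("planted perfect/one-mismatch proportions are recovered", {
  sim <- make_genome(seed = 506)
  rd <- make_srna_reads(sim$genome, n_reads = 10000,
                        perfect_fraction = 0.3, seed = 507)
  prof <- build_profile(rd$reads, sim$genome)[[1]]
  obs <- sum(prof$perfect_match) / sum(prof$total)
  ci_half <- qnorm(0.995) * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(obs - 0.3), ci_half)
  # read-by-read agreement between planted truth and profiler output
  mp <- map_reads(rd$reads, sim$genome)
  expect_true(all(mp$mapped))
  expect_equal(mp$mismatches, rd$truth$planted_mismatches)
})

test_that("fraction_perfect reports half-up percentages at 2 decimals", {
  counts <- load_srna_counts()
  p2 <- length_profile(counts$length, counts$gctv2_perfect,
                       counts$gctv2_1mm, "gctv2")
  p4 <- length_profile(counts$length, counts$gctv4_perfect,
                       counts$gctv4_1mm, "gctv4")
  expect_equal(fraction_perfect(p2), 2.23)   # 2097/94044 = 2.2298%
  # 841/111335 = 0.7554%; the source table prints 0.75 (truncated),
  # half-up rounding gives 0.76
  expect_equal(fraction_perfect(p4), 0.76)
  all_perfect <- length_profile("15", 100L, 0L)
  expect_equal(fraction_perfect(all_perfect), 100)
  empty <- length_profile(character(0), integer(0), integer(0))
  expect_warning(res <- fraction_perfect(empty), "undefined|empty")
  expect_true(is.na(res))
})

test_that("classification matches a re-aggregation oracle", {
  counts <- load_srna_counts()
  p2 <- length_profile(counts$length, counts$gctv2_perfect,
                       counts$gctv2_1mm, "gctv2")
  cls <- classify_lengths(p2)
  # published GcTV2 numbers: only ten 20-nt reads reach siRNA length
  expect_equal(unname(cls$counts["siRNA"]), 10L)
  lens <- suppressWarnings(as.integer(counts$length))
  usum <- sum(p2$total[!is.na(lens) & lens >= 13 & lens <= 19])
  expect_equal(unname(cls$counts["usRNA"]), usum)
  expect_equal(cls$modal_length, "10")
  expect_equal(sum(cls$counts), sum(p2$total))

  # random profiles re-aggregate consistently
  set.seed(508)
  for (rep in 1:10) {
    pm <- sample(0:50, 22, replace = TRUE)
    om <- sample(0:50, 22, replace = TRUE)
    pr <- length_profile(c(as.character(10:30), ">30"), pm, om)
    cl <- classify_lengths(pr)
    expect_equal(sum(cl$counts), sum(pm + om))
    expect_equal(unname(cl$counts["siRNA"]), sum((pm + om)[11:15]))
    expect_equal(unname(cl$counts["usRNA"]), sum((pm + om)[4:10]))
  }

  all15 <- length_profile("15", 40L, 60L)
  cls15 <- classify_lengths(all15)
  expect_equal(unname(cls15$counts["usRNA"]), 100L)
})

test_that("host-vs-virus mismatch contrast is reproduced on synthetic data", {
  # viral reads mostly carry one planted mismatch, host reads are mostly
  # perfect -- the control argument that mismatches are not sequencing
  # error
  host <- make_host_genome(20000L, gc = 0.5, seed = 509)
  sim <- make_genome(seed = 510)
  viral_rd <- make_srna_reads(sim$genome, 2000, perfect_fraction = 0.0223,
                              seed = 511)
  host_rd <- make_srna_reads(host, 2000, perfect_fraction = 0.219,
                             seed = 512, id_prefix = "h")
  vp <- build_profile(viral_rd$reads, sim$genome)[[1]]
  hp <- build_profile(host_rd$reads, host)[[1]]
  expect_lt(fraction_perfect(vp), 6)
  expect_gt(fraction_perfect(hp), 15)
})
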