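# Synthetic totivirus genomes, host background and small-RNA read sets
# with fully known planted structure.
#
# The generator's defaults reproduce the layout of the characterized
# ~4.6 kb totivirus GcTV2-Gc6: 29 nt 5' UTR, 2043 nt ORF1 (frame 3),
# 326 nt intergenic region, 2157 nt ORF2 (frame 2), 37 nt 3' UTR,
# GGGUUUA slippery heptamer ending 108 nt upstream of the ORF1 end on a
# codon boundary, a 4 nt spacer and a 55 nt H-type pseudoknot.  Every
# construction constraint needed for the planted structure to be the
# one the pipeline recovers (no internal stops in ORF or fusion frames,
# no start codon opening a competing long ORF across the frameshift
# region, no competing codon-boundary heptamer) is enforced at
# generation time; the rest of the sequence is random at the requested
# GC content.

# run expr with a local, seeded RNG; the caller's RNG state is restored
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
}

random_bases <- function(n, gc) {
  sample(RNA_BASES, n, replace = TRUE, prob = base_probs(gc))
}

random_nonstop_codons <- function(n, gc) {
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(random_bases(3 * n, gc), ncol = 3, byrow = TRUE)
    codons <- paste0(m[, 1], m[, 2], m[, 3])
    out <- c(out, codons[!(codons %in% STOP_CODONS)])
  }
  out[seq_len(n)]
}

#' Default parameters of the synthetic totivirus genome
#'
#' The stated world: the GcTV2-class layout described above.  Override
#' individual entries through the `params` argument of
#' [make_genome()].
#'
#' @return named list of generator parameters.
#' @export
genome_params <- function() {
  list(
    genome_length = 4592L,
    utr5 = 29L, ir = 326L, utr3 = 37L,
    orf1_nt = 2043L,                  # ORF2 length is implied
    slippery_upstream = 108L,         # ORF1 end - heptamer end
    heptamer = "GGGUUUA",
    spacer = 4L,
    stem1 = 6L, stem2 = 5L,           # pseudoknot stem lengths (bp)
    loops = c(2L, 11L, 20L),          # L1, L2, L3 (span = 55 nt)
    gc = 0.455,
    his_aa = 154L,                    # cap-snatching His in ORF1
    gdd_aa = 450L,                    # GDD motif start in ORF2
    max_resample = 1000L
  )
}

#' Parameters reproducing the second characterized genome layout
#'
#' GcTV4-class: 4530 nt, 5/20/35 nt UTR5/IR/UTR3, 2097 + 2373 nt ORFs,
#' UUUUUUA heptamer ending 153 nt upstream of the ORF1 end, 27 nt
#' spacer and a 21 nt pseudoknot.
#'
#' @return named list of generator parameters.
#' @export
genome_params_gctv4 <- function() {
  modifyList(genome_params(), list(
    genome_length = 4530L,
    utr5 = 5L, ir = 20L, utr3 = 35L,
    orf1_nt = 2097L,
    slippery_upstream = 153L,
    heptamer = "UUUUUUA",
    spacer = 27L,
    stem1 = 4L, stem2 = 3L,
    loops = c(1L, 2L, 4L),            # span = 21 nt
    gc = 0.426,
    gdd_aa = 460L
  ))
}

# resolve derived coordinates and validate parameter arithmetic
resolve_layout <- function(p) {
  orf1_start <- p$utr5 + 1L
  orf1_end <- p$utr5 + p$orf1_nt
  orf2_start <- orf1_end + p$ir + 1L
  orf2_nt <- p$genome_length - p$utr5 - p$orf1_nt - p$ir - p$utr3
  orf2_end <- orf2_start + orf2_nt - 1L
  he <- orf1_end - p$slippery_upstream
  pk_start <- he + p$spacer + 1L
  pk_span <- 2L * (p$stem1 + p$stem2) + sum(p$loops)
  pk_end <- pk_start + pk_span - 1L
  fail <- function(msg) stop("inconsistent parameters: ", msg, call. = FALSE)
  if (orf2_nt < 6L) fail("segment lengths exceed genome length")
  if (p$orf1_nt %% 3L != 0L) fail("orf1_nt not divisible by 3")
  if (orf2_nt %% 3L != 0L) fail("implied orf2_nt not divisible by 3")
  if (orf2_end + p$utr3 != p$genome_length)
    fail("segments do not sum to genome_length")
  if (!is_slippery_heptamer(p$heptamer)) fail("heptamer not canonical")
  if ((he - orf1_start + 1L) %% 3L != 0L)
    fail("slippery end not on an ORF1 codon boundary")
  if ((orf2_start - he) %% 3L != 0L)
    fail("post-shift frame inconsistent with ORF2 frame")
  if (he - 9L <= orf1_start + 2L) fail("heptamer too close to ORF1 start")
  if (pk_end >= orf2_start) fail("pseudoknot runs into ORF2")
  if (p$spacer < 1L) fail("spacer must be at least 1 nt")
  if (any(p$loops < 1L))
    fail("planted loops must each be at least 1 nt (guard bases)")
  if (p$his_aa < 2L || 3L * p$his_aa > he - orf1_start - 12L)
    fail("his_aa collides with the frameshift region")
  if (p$gdd_aa < 2L || p$gdd_aa + 3L > orf2_nt %/% 3L)
    fail("gdd_aa outside ORF2")
  list(orf1_start = orf1_start, orf1_end = orf1_end,
       orf2_start = orf2_start, orf2_end = orf2_end, orf2_nt = orf2_nt,
       he = he, pk_start = pk_start, pk_end = pk_end, pk_span = pk_span)
}

# positions of the pseudoknot segments given its 5' start
pk_segments <- function(pk_start, s1, s2, loops) {
  s1a <- pk_start:(pk_start + s1 - 1L)
  l1 <- if (loops[1] > 0L) (max(s1a) + 1L):(max(s1a) + loops[1]) else integer(0)
  s2a <- (max(s1a) + loops[1] + 1L):(max(s1a) + loops[1] + s2)
  l2 <- if (loops[2] > 0L) (max(s2a) + 1L):(max(s2a) + loops[2]) else integer(0)
  s1b <- (max(s2a) + loops[2] + 1L):(max(s2a) + loops[2] + s1)
  l3 <- if (loops[3] > 0L) (max(s1b) + 1L):(max(s1b) + loops[3]) else integer(0)
  s2b <- (max(s1b) + loops[3] + 1L):(max(s1b) + loops[3] + s2)
  list(s1a = s1a, l1 = l1, s2a = s2a, l2 = l2, s1b = s1b, l3 = l3,
       s2b = s2b)
}

#' Generate a totivirus-like genome with planted, fully known structure
#'
#' Produces a random genome realizing the requested layout exactly:
#' two long ORFs in different frames, a canonical slippery heptamer
#' ending on an ORF1 codon boundary, a planted H-type pseudoknot (GC
#' stems, so it is the strongest structure in its window under the
#' package energy model), a conserved His codon in ORF1, a GDD
#' tripeptide in ORF2, and a stop-free -1 frameshift fusion frame.
#' The genome is resampled (up to `max_resample` times) until the
#' annotation and PRF pipeline provably recover exactly the planted
#' structure; the planted coordinates are returned as the truth object.
#'
#' @param params list of generator parameters ([genome_params()]
#'   entries; partial lists are merged over the defaults).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param id genome identifier.
#' @return list with `genome` (a [genome_record()]) and `truth` (class
#'   `synthetic_truth`).
#' @export
make_genome <- function(params = list(), seed = 1L, id = "synthetic_totivirus") {
  p <- modifyList(genome_params(), params)
  ly <- resolve_layout(p)
  with_local_seed(seed, {
    for (attempt in seq_len(p$max_resample)) {
      g <- build_genome_once(p, ly, id)
      if (!is.null(g)) {
        truth <- validate_planted(g, p, ly, seed)
        if (!is.null(truth)) {
          return(list(genome = g, truth = truth))
        }
      }
    }
    stop("failed to realize the requested layout after ",
         p$max_resample, " resamples", call. = FALSE)
  })
}

# one construction attempt; returns a genome_record or NULL when the
# constrained fill fails
build_genome_once <- function(p, ly, id) {
  x <- character(p$genome_length)
  gc <- p$gc
  # UTR5 + ORF1 body
  if (p$utr5 > 0L) x[1:p$utr5] <- random_bases(p$utr5, gc)
  n1_codons <- p$orf1_nt %/% 3L
  body <- random_nonstop_codons(n1_codons - 2L, gc)
  orf1_seq <- c("AUG", body, "UAA")
  x[ly$orf1_start:ly$orf1_end] <-
    unlist(strsplit(orf1_seq, ""), use.names = FALSE)
  # conserved His codon in ORF1
  his_nt <- ly$orf1_start + 3L * (p$his_aa - 1L)
  x[his_nt:(his_nt + 2L)] <- c("C", "A", sample(c("U", "C"), 1L))
  # slippery heptamer, 3' end on the ORF1 codon grid
  x[(ly$he - 6L):ly$he] <- strsplit(p$heptamer, "")[[1]]
  # frame -1 "roadblock" stop immediately upstream of the heptamer:
  # guarantees no upstream AUG can read through into ORF2's frame
  x[(ly$he - 9L):(ly$he - 7L)] <- c("U", "A", "A")
  # intergenic region (constrained fill below overwrites its bases)
  if (p$ir > 0L) {
    x[(ly$orf1_end + 1L):(ly$orf2_start - 1L)] <- random_bases(p$ir, gc)
  }
  # ORF2 with planted GDD
  n2_codons <- ly$orf2_nt %/% 3L
  body2 <- random_nonstop_codons(n2_codons - 2L, gc)
  gdd_idx <- p$gdd_aa - 1L  # index into body2 (body2[1] is codon 2)
  body2[gdd_idx:(gdd_idx + 2L)] <- c("GGU", "GAU", "GAC")
  orf2_seq <- c("AUG", body2, "UAA")
  x[ly$orf2_start:ly$orf2_end] <-
    unlist(strsplit(orf2_seq, ""), use.names = FALSE)
  # UTR3
  if (p$utr3 > 0L) {
    x[(ly$orf2_end + 1L):p$genome_length] <- random_bases(p$utr3, gc)
  }
  # pseudoknot: GC stems (constraint-safe in every frame), random loops
  seg <- pk_segments(ly$pk_start, p$stem1, p$stem2, p$loops)
  s1a <- sample(c("G", "C"), p$stem1, replace = TRUE)
  s2a <- sample(c("G", "C"), p$stem2, replace = TRUE)
  x[seg$s1a] <- s1a
  x[seg$s1b] <- rev(chartr("GC", "CG", s1a))
  x[seg$s2a] <- s2a
  x[seg$s2b] <- rev(chartr("GC", "CG", s2a))
  # A.A guard bases at every stem junction: A pairs only with U, so no
  # enumerated helix can extend a planted stem and displace the planted
  # span as the best-scoring candidate
  guards <- c(min(seg$s1a) - 1L, max(seg$s2b) + 1L,   # stem1/stem2 outward
              min(seg$s1a) + p$stem1, min(seg$s1b) - 1L,  # stem1 inward
              min(seg$s2a) + p$stem2, min(seg$s2b) - 1L,  # stem2 inward
              min(seg$s2a) - 1L, max(seg$s1b) + 1L)   # stem2 out / L1-L3 ends
  guards <- guards[guards >= 1L & guards <= p$genome_length]
  x[guards] <- "A"
  fixed <- rep(FALSE, p$genome_length)
  fixed[guards] <- TRUE
  fixed[c(seg$s1a, seg$s1b, seg$s2a, seg$s2b)] <- TRUE
  fixed[(ly$he - 9L):ly$he] <- TRUE
  fixed[(ly$orf1_end - 2L):ly$orf1_end] <- TRUE  # ORF1 stop
  fixed[his_nt:(his_nt + 2L)] <- TRUE
  # constrained fill of the frameshift region [he+1, orf2_start-1]:
  # ORF1 codons stay stop-free, and every codon of the -1 fusion frame
  # (starting at the heptamer 3' end) is neither a stop nor an AUG
  x <- constrained_fill(x, p, ly, fixed)
  if (is.null(x)) return(NULL)
  genome_record(id, paste(x, collapse = ""))
}

# left-to-right fill of the frameshift region with per-position repair
constrained_fill <- function(x, p, ly, fixed) {
  gc <- p$gc
  pr <- base_probs(gc)
  region <- (ly$he + 1L):(ly$orf2_start - 1L)
  for (pos in region) {
    if (!fixed[pos]) x[pos] <- sample(RNA_BASES, 1L, prob = pr)
    # codons ending at pos
    allowed <- RNA_BASES
    bad <- character(0)
    # ORF1 frame: no internal stop (the planted stop itself is exempt)
    if (pos >= ly$orf1_start + 2L && pos <= ly$orf1_end - 3L &&
        (pos - ly$orf1_start + 1L) %% 3L == 0L) {
      prefix <- paste0(x[pos - 2L], x[pos - 1L])
      bad <- c(bad, substring(STOP_CODONS[startsWith(STOP_CODONS, prefix)],
                              3L, 3L))
    }
    # fusion (-1) frame: no stop, no AUG
    if (pos >= ly$he + 2L && (pos - ly$he) %% 3L == 2L) {
      prefix <- paste0(x[pos - 2L], x[pos - 1L])
      forb <- c(STOP_CODONS, "AUG")
      bad <- c(bad, substring(forb[startsWith(forb, prefix)], 3L, 3L))
    }
    if (length(bad) == 0L) next
    if (fixed[pos]) {
      if (x[pos] %in% bad) return(NULL)  # rare clash with planted bases
      next
    }
    allowed <- setdiff(RNA_BASES, bad)
    if (x[pos] %in% bad) {
      x[pos] <- sample(allowed, 1L, prob = pr[allowed] / sum(pr[allowed]))
    }
  }
  x
}

# confirm the pipeline recovers exactly the planted structure; returns
# the truth object, or NULL to trigger a resample
validate_planted <- function(genome, p, ly, seed) {
  ann <- tryCatch(annotate(genome, min_aa = 100L), error = function(e) NULL)
  if (is.null(ann)) return(NULL)
  if (ann$orf1$interval$start != ly$orf1_start ||
      ann$orf1$interval$end != ly$orf1_end ||
      ann$orf2$interval$start != ly$orf2_start ||
      ann$orf2$interval$end != ly$orf2_end) return(NULL)
  sites <- scan_slippery(genome, ann$orf1, max_upstream = 200L)
  if (length(sites) != 1L) return(NULL)
  if (sites[[1L]]$interval$end != ly$he ||
      sites[[1L]]$heptamer != p$heptamer) return(NULL)
  scan <- prf_scan(genome, ann$orf1, ann$orf2)
  if (is.null(scan$best)) return(NULL)
  if (scan$best$spacer_length != p$spacer ||
      scan$best$pseudoknot$span$start != ly$pk_start ||
      scan$best$pseudoknot$span$end != ly$pk_end) return(NULL)
  fus <- tryCatch(
    fusion_protein(genome, ann$orf1, sites[[1L]], ann$orf2),
    error = function(e) NULL)
  if (is.null(fus)) return(NULL)
  expected_fusion <- (ly$he - ly$orf1_start + 1L) %/% 3L +
    (ly$orf2_end - 3L - ly$he + 1L) %/% 3L
  if (fus$protein_length != expected_fusion) return(NULL)
  seg <- pk_segments(ly$pk_start, p$stem1, p$stem2, p$loops)
  structure(
    list(genome_id = genome$id, genome_length = p$genome_length,
         utr5 = c(1L, p$utr5),
         orf1 = c(ly$orf1_start, ly$orf1_end),
         intergenic = c(ly$orf1_end + 1L, ly$orf2_start - 1L),
         orf2 = c(ly$orf2_start, ly$orf2_end),
         utr3 = c(ly$orf2_end + 1L, p$genome_length),
         slippery = c(ly$he - 6L, ly$he), heptamer = p$heptamer,
         spacer = p$spacer,
         pk_span = c(ly$pk_start, ly$pk_end),
         pk_stem1 = cbind(seg$s1a, rev(seg$s1b)),
         pk_stem2 = cbind(seg$s2a, rev(seg$s2b)),
         fusion_aa = expected_fusion,
         his_aa = p$his_aa, gdd_aa = p$gdd_aa,
         seed = seed),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %s: ORF1 %d-%d, ORF2 %d-%d, %s @%d-%d, spacer %d, pk %d-%d, fusion %d aa\n",
    x$genome_id, x$orf1[1], x$orf1[2], x$orf2[1], x$orf2[2], x$heptamer,
    x$slippery[1], x$slippery[2], x$spacer, x$pk_span[1], x$pk_span[2],
    x$fusion_aa))
  invisible(x)
}

#' Published-shape default length distribution for synthetic viral reads
#'
#' Probabilities proportional to the per-length totals observed for the
#' GcTV2-class virus-derived sRNA population (lengths 10-20 nt, heavily
#' skewed to 10-13 nt).
#'
#' @return named numeric vector of probabilities.
#' @export
srna_length_dist <- function() {
  counts <- c(`10` = 56987, `11` = 15616, `12` = 7309, `13` = 12614,
              `14` = 615, `15` = 369, `16` = 47, `17` = 133,
              `18` = 337, `19` = 7, `20` = 10)
  counts / sum(counts)
}

#' Simulate a small-RNA read set with planted mismatch truth
#'
#' Each read is a substring of a randomly chosen target (reverse
#' complemented for minus-strand reads) carrying exactly 0 or 1 planted
#' substitutions.  The planted mismatch count is guaranteed to be the
#' read's true minimum Hamming distance over all placements on its
#' origin target (reads whose mutation is shadowed by an accidental
#' perfect match elsewhere are re-drawn), so profiler output can be
#' compared to the truth read by read.
#'
#' @param targets a [genome_record()] or list of them.
#' @param n_reads number of reads.
#' @param length_dist named probability vector over read lengths
#'   (default [srna_length_dist()]).
#' @param perfect_fraction probability a read carries no mismatch
#'   (default 0.0223, the perfect-match fraction observed for the
#'   GcTV2-class viral population).
#' @param strand_fraction probability of the plus strand (default 0.5).
#' @param seed integer seed.
#' @param id_prefix read identifier prefix.
#' @return list with `reads` (an `srna_set`) and `truth` (data.frame:
#'   read_id, target_id, offset, strand, planted_mismatches, length).
#' @export
make_srna_reads <- function(targets, n_reads,
                            length_dist = srna_length_dist(),
                            perfect_fraction = 0.0223,
                            strand_fraction = 0.5, seed = 1L,
                            id_prefix = "sr") {
  if (inherits(targets, "genome_record")) targets <- list(targets)
  stopifnot(n_reads >= 1L,
            perfect_fraction >= 0, perfect_fraction <= 1,
            strand_fraction >= 0, strand_fraction <= 1)
  lens_avail <- as.integer(names(length_dist))
  stopifnot(!any(is.na(lens_avail)), all(lens_avail >= 10L))
  min_target_len <- min(vapply(targets, function(t) t$length, integer(1)))
  if (max(lens_avail) > min_target_len) {
    stop("requested read length exceeds target length", call. = FALSE)
  }
  with_local_seed(seed, {
    tgt_idx <- sample.int(length(targets), n_reads, replace = TRUE)
    lens <- sample(lens_avail, n_reads, replace = TRUE, prob = length_dist)
    perfect <- runif(n_reads) < perfect_fraction
    strands <- ifelse(runif(n_reads) < strand_fraction, "+", "-")
    seqs <- character(n_reads)
    offs <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      tg <- targets[[tgt_idx[i]]]
      for (try in 1:100) {
        off <- sample.int(tg$length - lens[i] + 1L, 1L)
        s <- substr(tg$sequence, off, off + lens[i] - 1L)
        if (strands[i] == "-") s <- revcomp_rna(s)
        if (!perfect[i]) {
          mpos <- sample.int(lens[i], 1L)
          old <- substr(s, mpos, mpos)
          new <- sample(setdiff(RNA_BASES, old), 1L)
          substr(s, mpos, mpos) <- new
        }
        # the planted count must be the true minimal distance
        got <- .map_read_cpp(tg$sequence, s, 1L)
        if (isTRUE(got$mapped) && got$mismatches == (!perfect[i])) {
          seqs[i] <- s
          offs[i] <- off
          break
        }
        if (try == 100L) {
          stop("could not realize planted mismatch count for read ", i,
               call. = FALSE)
        }
      }
    }
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_reads))
    truth <- data.frame(
      read_id = ids,
      target_id = vapply(targets, function(t) t$id, character(1))[tgt_idx],
      offset = offs, strand = strands,
      planted_mismatches = as.integer(!perfect), length = lens,
      stringsAsFactors = FALSE)
    list(reads = srna_set(ids, seqs), truth = truth)
  })
}

#' Generate an i.i.d. host background genome
#'
#' Stands in for the host reference assembly in mapping controls.
#'
#' @param length genome length in nt (at least 1 kb).
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @param id sequence identifier.
#' @return a [genome_record()].
#' @export
make_host_genome <- function(length, gc = 0.5, seed = 1L,
                             id = "synthetic_host") {
  stopifnot(length >= 1000L, gc >= 0, gc <= 1)
  with_local_seed(seed, {
    genome_record(id, paste(random_bases(length, gc), collapse = ""))
  })
}
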