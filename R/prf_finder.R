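# -1 programmed ribosomal frameshift (PRF) element detection.
#
# A -1 PRF element is a slippery heptamer X XXY YYZ near the ORF1 stop,
# a short spacer, and a downstream H-type pseudoknot that stalls the
# ribosome.  Although some prose describes the pseudoknot as "preceding"
# the slippery site, every mapped totivirus element (and the -1 PRF
# literature) places it downstream of the heptamer, which is the
# orientation searched here.

# allowed pairs in stems: Watson-Crick + G.U wobble
PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
PAIRABLE["A", "U"] <- PAIRABLE["U", "A"] <- TRUE
PAIRABLE["G", "C"] <- PAIRABLE["C", "G"] <- TRUE
PAIRABLE["G", "U"] <- PAIRABLE["U", "G"] <- TRUE

# per-pair stacking surrogate (kcal/mol)
PAIR_ENERGY <- c(GC = -3.0, CG = -3.0, AU = -2.0, UA = -2.0,
                 GU = -1.0, UG = -1.0)
LOOP_PENALTY_PER_NT <- 0.2
PK_INIT_PENALTY <- 7.0

#' Test the canonical slippery-heptamer grammar
#'
#' A canonical -1 PRF slippery site is `XXXYYYZ` with the three X
#' identical (any base), the three Y identical and in `{A,U}`, and
#' `Z` in `{A,C,U}`.
#'
#' @param heptamer 7-nt RNA string.
#' @return logical.
#' @examples
#' is_slippery_heptamer("GGGUUUA")  # TRUE
#' is_slippery_heptamer("GGGUUUG")  # FALSE (Z = G)
#' @export
is_slippery_heptamer <- function(heptamer) {
  if (nchar(heptamer) != 7L) return(FALSE)
  b <- strsplit(heptamer, "")[[1]]
  all(b %in% RNA_BASES) &&
    b[1] == b[2] && b[2] == b[3] &&
    b[4] == b[5] && b[5] == b[6] && b[4] %in% c("A", "U") &&
    b[7] %in% c("A", "C", "U")
}

#' Scan for slippery heptamers near the ORF1 stop
#'
#' Finds every heptamer matching the canonical grammar whose interval
#' lies within `[orf1.end - max_upstream, orf1.end]`, annotated with the
#' distance to the ORF1 end and whether its 3' end falls on an ORF1
#' codon boundary (`(end - orf1.start + 1) %% 3 == 0`).  Both reported
#' totivirus heptamers sit on a codon boundary, and the frameshift
#' arithmetic requires it, so non-boundary hits are dropped by default.
#'
#' @param genome a [genome_record()].
#' @param orf1 `orf_annotation` for the 5' ORF.
#' @param max_upstream how far upstream of the ORF1 end to scan
#'   (default 200 nt; the characterized sites lie ~110-150 nt upstream).
#' @param require_codon_boundary drop hits whose 3' end is off the ORF1
#'   codon grid (default TRUE).
#' @return list of `slippery_site` objects sorted 5' to 3'.
#' @export
scan_slippery <- function(genome, orf1, max_upstream = 200L,
                          require_codon_boundary = TRUE) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(orf1, "orf_annotation"))
  lo <- max(1L, orf1$interval$end - as.integer(max_upstream))
  hi <- orf1$interval$end
  if (hi - lo + 1L < 7L) return(list())
  starts <- lo:(hi - 6L)
  heps <- substring(genome$sequence, starts, starts + 6L)
  keep <- vapply(heps, is_slippery_heptamer, logical(1), USE.NAMES = FALSE)
  out <- list()
  for (i in which(keep)) {
    s <- starts[i]; e <- s + 6L
    on_boundary <- (e - orf1$interval$start + 1L) %% 3L == 0L
    if (require_codon_boundary && !on_boundary) next
    b <- strsplit(heps[i], "")[[1]]
    out[[length(out) + 1L]] <- structure(
      list(interval = interval(s, e), heptamer = heps[i],
           x = b[1], y = b[4], z = b[7],
           distance_to_orf1_stop = orf1$interval$end - e,
           on_codon_boundary = on_boundary),
      class = "slippery_site")
  }
  out
}

#' @export
print.slippery_site <- function(x, ...) {
  cat(sprintf("<slippery_site> %s at %d-%d (%d nt upstream of ORF1 end%s)\n",
              x$heptamer, x$interval$start, x$interval$end,
              x$distance_to_orf1_stop,
              if (x$on_codon_boundary) ", codon boundary" else ""))
  invisible(x)
}

#' Pseudoknot search parameters
#'
#' Bounds for the exhaustive H-type pseudoknot enumeration.  Loop
#' bounds follow the layout `S1a - L1 - S2a - L2 - S1b - L3 - S2b`
#' (stem 2 pairs loop-1 nucleotides of stem 1 with a region downstream
#' of stem 1's 3' half, so the stems cross).
#'
#' @param min_stem,max_stem stem length bounds in base pairs.
#' @param loop1,loop2,loop3 length-2 integer vectors, inclusive bounds
#'   for the three loops in nt (`loop2` may be zero).
#' @param max_span maximum pseudoknot span in nt.
#' @param max_window maximum scan window accepted by
#'   [find_pseudoknots()].
#' @return list of class `pk_params`.
#' @export
pk_params <- function(min_stem = 3L, max_stem = 10L,
                      loop1 = c(1L, 10L), loop2 = c(0L, 20L),
                      loop3 = c(1L, 40L), max_span = 80L,
                      max_window = 120L) {
  p <- list(min_stem = as.integer(min_stem), max_stem = as.integer(max_stem),
            loop1 = as.integer(loop1), loop2 = as.integer(loop2),
            loop3 = as.integer(loop3), max_span = as.integer(max_span),
            max_window = as.integer(max_window))
  stopifnot(p$min_stem >= 2L, p$max_stem >= p$min_stem,
            length(p$loop1) == 2L, length(p$loop2) == 2L,
            length(p$loop3) == 2L)
  class(p) <- "pk_params"
  p
}

pk_pairable <- function(a, b) {
  a %in% RNA_BASES & b %in% RNA_BASES &
    PAIRABLE[cbind(match(a, RNA_BASES), match(b, RNA_BASES))]
}

#' Energy of a pseudoknot under the additive surrogate model
#'
#' `energy = sum(per-pair terms) + 0.2 kcal/mol per unpaired loop nt +
#' 7.0 kcal/mol initiation penalty`, with per-pair terms GC = -3.0,
#' AU = -2.0, GU = -1.0 kcal/mol.  This is a deliberately simple,
#' fully reproducible surrogate for a thermodynamic folding energy: it
#' ranks candidate structures (more/stronger pairs and shorter loops
#' win) but is not comparable to Turner-model free energies.
#'
#' @param pk a `pseudoknot` object.
#' @param params a [pk_params()] (unused by the default model; kept in
#'   the signature so alternative models can be slotted in).
#' @return energy in kcal/mol (lower = more stable).
#' @export
pk_energy <- function(pk, params = pk_params()) {
  stopifnot(inherits(pk, "pseudoknot"))
  seq_chars <- attr(pk, "seq_chars")
  pair_term <- function(stem) {
    if (nrow(stem) == 0L) return(0)
    key <- paste0(seq_chars[stem[, 1L]], seq_chars[stem[, 2L]])
    sum(PAIR_ENERGY[key])
  }
  sum_pairs <- pair_term(pk$stem1) + pair_term(pk$stem2)
  loop_nt <- sum(pk$loop_lengths)
  sum_pairs + LOOP_PENALTY_PER_NT * loop_nt + PK_INIT_PENALTY
}

make_pseudoknot <- function(seq_chars, offset, i1, j1, s1, i2, j2, s2) {
  # coordinates are genome positions; i = 5' start of the 5' half,
  # j = 3' end of the 3' half, s = stem length
  stem1 <- cbind(i1:(i1 + s1 - 1L), j1:(j1 - s1 + 1L))
  stem2 <- cbind(i2:(i2 + s2 - 1L), j2:(j2 - s2 + 1L))
  l1 <- i2 - (i1 + s1)
  l2 <- (j1 - s1 + 1L) - (i2 + s2)
  l3 <- (j2 - s2 + 1L) - j1 - 1L
  pk <- structure(
    list(stem1 = stem1, stem2 = stem2,
         span = interval(i1, j2),
         loop_lengths = c(L1 = l1, L2 = l2, L3 = l3),
         efe_kcal_mol = NA_real_),
    class = "pseudoknot")
  attr(pk, "seq_chars") <- seq_chars
  pk$efe_kcal_mol <- pk_energy(pk)
  pk
}

#' Exhaustively enumerate H-type pseudoknots in a window
#'
#' Enumerates every pair of crossing stems (Watson-Crick or G.U pairs)
#' satisfying the stem-length, loop-length and span bounds in `params`,
#' scores each with [pk_energy()], deduplicates candidates sharing a
#' span (best energy kept), and returns them sorted by energy (ties:
#' smaller span, then 5'-most start).
#'
#' Layout searched: `S1a - L1 - S2a - L2 - S1b - L3 - S2b`, where S1a/S1b
#' and S2a/S2b are the paired halves; every stem-2 pair has its 5'
#' partner inside stem 1's loop and its 3' partner downstream of stem
#' 1's 3' half, so the stems cross (H-type).
#'
#' @param genome a [genome_record()].
#' @param window an [interval()] within the genome, at most
#'   `params$max_window` nt wide.
#' @param params a [pk_params()].
#' @return list of `pseudoknot` objects (genome coordinates).
#' @export
find_pseudoknots <- function(genome, window, params = pk_params()) {
  stopifnot(inherits(genome, "genome_record"), inherits(window, "interval"))
  check_interval_in_genome(window, genome$length)
  w <- interval_length(window)
  if (w > params$max_window) {
    stop(sprintf(
      "window of %d nt exceeds max_window = %d; scan a narrower window",
      w, params$max_window), call. = FALSE)
  }
  seq_chars <- strsplit(genome$sequence, "")[[1]]
  wchars <- seq_chars[window$start:window$end]
  helix <- enumerate_helices(wchars, params$min_stem, params$max_stem)
  if (nrow(helix) == 0L) return(list())
  # pair stem1 (rows a) with stem2 (rows b) under the H-type geometry
  na <- nrow(helix)
  idx <- expand.grid(a = seq_len(na), b = seq_len(na))
  i1 <- helix$i[idx$a]; j1 <- helix$j[idx$a]; s1 <- helix$s[idx$a]
  i2 <- helix$i[idx$b]; j2 <- helix$j[idx$b]; s2 <- helix$s[idx$b]
  l1 <- i2 - (i1 + s1)
  l2 <- (j1 - s1 + 1L) - (i2 + s2)
  l3 <- (j2 - s2 + 1L) - j1 - 1L
  ok <- l1 >= params$loop1[1] & l1 <= params$loop1[2] &
    l2 >= params$loop2[1] & l2 <= params$loop2[2] &
    l3 >= params$loop3[1] & l3 <= params$loop3[2] &
    (j2 - i1 + 1L) <= params$max_span
  if (!any(ok)) return(list())
  keep <- which(ok)
  # vectorized energies: per-helix pair-energy sums are additive, so
  # score all candidates before building any objects
  helix_e <- helix_pair_energy(wchars, helix)
  e <- helix_e[idx$a[keep]] + helix_e[idx$b[keep]] +
    LOOP_PENALTY_PER_NT * (l1[keep] + l2[keep] + l3[keep]) +
    PK_INIT_PENALTY
  width <- (j2 - i1 + 1L)[keep]
  ord <- order(e, width, i1[keep])
  keep <- keep[ord]
  span_key <- paste(i1[keep], j2[keep])
  keep <- keep[!duplicated(span_key)]
  off <- window$start - 1L
  lapply(keep, function(k) {
    make_pseudoknot(seq_chars, off,
                    i1[k] + off, j1[k] + off, s1[k],
                    i2[k] + off, j2[k] + off, s2[k])
  })
}

# Sum of per-pair energy terms for each helix row (i, j, s).
helix_pair_energy <- function(wchars, helix) {
  vapply(seq_len(nrow(helix)), function(r) {
    i <- helix$i[r]; j <- helix$j[r]; s <- helix$s[r]
    k <- 0:(s - 1L)
    sum(PAIR_ENERGY[paste0(wchars[i + k], wchars[j - k])])
  }, numeric(1))
}

# All helices (i, j, s): positions i..i+s-1 pair with j..j-s+1 within a
# character window; i/j are window-local 1-based.  Returns every stem
# length in [min_stem, max_stem] realizable at each (i, j).
enumerate_helices <- function(wchars, min_stem, max_stem) {
  n <- length(wchars)
  if (n < 2L * min_stem + 1L) {
    return(data.frame(i = integer(), j = integer(), s = integer()))
  }
  comp <- outer(wchars, wchars, pk_pairable)
  # inward run length: D[i,j] = comp[i,j] ? 1 + D[i+1, j-1] : 0
  D <- matrix(0L, n, n)
  for (i in n:1) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (comp[i, j]) {
        D[i, j] <- 1L + if (i + 1L <= n && j - 1L >= 1L && j - 1L > i + 1L)
          D[i + 1L, j - 1L] else 0L
      }
    }
  }
  hits <- which(D >= min_stem, arr.ind = TRUE)
  dimnames(hits) <- NULL
  if (nrow(hits) == 0L) {
    return(data.frame(i = integer(), j = integer(), s = integer()))
  }
  res <- vector("list", nrow(hits))
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1L]; j <- hits[r, 2L]
    smax <- min(max_stem, D[i, j], (j - i) %/% 2L)
    if (smax < min_stem) next
    s <- min_stem:smax
    res[[r]] <- data.frame(i = i, j = j, s = s)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(i = integer(), j = integer(), s = integer())
  else out
}

#' @export
print.pseudoknot <- function(x, ...) {
  cat(sprintf(
    "<pseudoknot> span %d-%d, stems %d+%d bp, loops %d/%d/%d, efe %.1f kcal/mol\n",
    x$span$start, x$span$end, nrow(x$stem1), nrow(x$stem2),
    x$loop_lengths[1], x$loop_lengths[2], x$loop_lengths[3],
    x$efe_kcal_mol))
  invisible(x)
}

#' Assemble PRF elements from a slippery site and pseudoknot candidates
#'
#' Combines one slippery site with each downstream pseudoknot whose
#' spacer (nt between the heptamer 3' end and the pseudoknot 5' end)
#' falls within `spacer_bounds`.  Elements are scored by pseudoknot
#' energy (lower = better) and returned best first.
#'
#' @param slippery a `slippery_site`.
#' @param pks list of `pseudoknot` objects.
#' @param spacer_bounds inclusive spacer bounds in nt (default
#'   `c(1, 30)`; characterized totivirus spacers are 4 and 27 nt).
#' @return list of `prf_element` objects.
#' @export
assemble_prf <- function(slippery, pks, spacer_bounds = c(1L, 30L)) {
  stopifnot(inherits(slippery, "slippery_site"))
  out <- list()
  for (pk in pks) {
    spacer <- pk$span$start - slippery$interval$end - 1L
    if (spacer < spacer_bounds[1] || spacer > spacer_bounds[2]) next
    out[[length(out) + 1L]] <- structure(
      list(slippery = slippery, spacer_length = spacer, pseudoknot = pk,
           score = pk$efe_kcal_mol),
      class = "prf_element")
  }
  out[order(vapply(out, function(e) e$score, numeric(1)))]
}

#' @export
print.prf_element <- function(x, ...) {
  cat(sprintf(
    "<prf_element> %s @%d-%d + %d nt spacer + pseudoknot %d-%d (efe %.1f)\n",
    x$slippery$heptamer, x$slippery$interval$start, x$slippery$interval$end,
    x$spacer_length, x$pseudoknot$span$start, x$pseudoknot$span$end,
    x$score))
  invisible(x)
}

#' Derive the ORF1-ORF2 fusion protein produced by a -1 frameshift
#'
#' At the slippery site the ribosome slips one nucleotide backwards, so
#' the final heptamer base is read twice: translation covers ORF1 codons
#' up to the heptamer 3' end, then resumes at that same position in the
#' -1 frame and runs to the codon before the ORF2 stop.  Preconditions
#' checked: the heptamer 3' end must fall on an ORF1 codon boundary and
#' the post-shift frame must be ORF2's frame.
#'
#' @param genome a [genome_record()].
#' @param orf1,orf2 `orf_annotation` objects.
#' @param slippery a `slippery_site` (only its 3' end is used).
#' @return list of class `fusion_product` with fields
#'   `pre_shift_codons`, `post_shift_codons`, `protein`,
#'   `protein_length`, `mass_kda`.
#' @export
fusion_protein <- function(genome, orf1, slippery, orf2) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(orf1, "orf_annotation"),
            inherits(orf2, "orf_annotation"),
            inherits(slippery, "slippery_site"))
  se <- slippery$interval$end
  if ((se - orf1$interval$start + 1L) %% 3L != 0L) {
    stop(sprintf(
      "slippery end %d is not on an ORF1 codon boundary ((end - start + 1) %%%% 3 != 0)",
      se), call. = FALSE)
  }
  if ((orf2$interval$start - se) %% 3L != 0L) {
    stop(sprintf(
      "post-shift frame at %d is inconsistent with ORF2 start %d ((orf2.start - end) %%%% 3 != 0)",
      se, orf2$interval$start), call. = FALSE)
  }
  pre_nt <- se - orf1$interval$start + 1L
  pre_codons <- pre_nt %/% 3L
  post_start <- se              # the -1 slip re-reads the final heptamer base
  post_end <- orf2$interval$end - 3L  # codon before the ORF2 stop
  post_nt <- post_end - post_start + 1L
  post_codons <- post_nt %/% 3L
  pre_seq <- substr(genome$sequence, orf1$interval$start, se)
  post_seq <- substr(genome$sequence, post_start, post_end)
  pre_aa <- translate_rna(pre_seq)
  post_aa <- translate_rna(post_seq)
  if (nchar(pre_aa) != pre_codons) {
    stop("internal stop in fusion protein at pre-shift codon ",
         nchar(pre_aa) + 1L, call. = FALSE)
  }
  if (nchar(post_aa) != post_codons) {
    stop("internal stop in fusion protein at post-shift codon ",
         nchar(post_aa) + 1L, " (genome position ",
         post_start + 3L * nchar(post_aa), ")", call. = FALSE)
  }
  protein <- paste0(pre_aa, post_aa)
  structure(
    list(pre_shift_codons = pre_codons, post_shift_codons = post_codons,
         protein = protein, protein_length = nchar(protein),
         mass_kda = protein_mass(protein)),
    class = "fusion_product")
}

#' @export
print.fusion_product <- function(x, ...) {
  cat(sprintf("<fusion_product> %d + %d = %d aa, %.2f kDa\n",
              x$pre_shift_codons, x$post_shift_codons, x$protein_length,
              x$mass_kda))
  invisible(x)
}

#' Scan for a complete PRF element downstream of ORF1
#'
#' Convenience wrapper: scans for codon-boundary slippery sites near
#' the ORF1 stop, enumerates pseudoknots in a window downstream of each
#' and assembles scored elements.
#'
#' @param genome a [genome_record()].
#' @param orf1,orf2 `orf_annotation` objects.
#' @param max_upstream see [scan_slippery()].
#' @param spacer_bounds see [assemble_prf()].
#' @param params see [pk_params()].
#' @param window_width nt scanned downstream of each heptamer for
#'   pseudoknots (default 100).
#' @return list with `elements` (all candidates, best first) and `best`
#'   (best element or NULL).
#' @export
prf_scan <- function(genome, orf1, orf2, max_upstream = 200L,
                     spacer_bounds = c(1L, 30L), params = pk_params(),
                     window_width = 100L) {
  sites <- scan_slippery(genome, orf1, max_upstream = max_upstream)
  elements <- list()
  for (s in sites) {
    lo <- s$interval$end + 1L
    hi <- min(genome$length, s$interval$end + window_width)
    if (hi - lo + 1L < 2L * 3L + 1L) next
    pks <- find_pseudoknots(genome, interval(lo, hi), params)
    elements <- c(elements, assemble_prf(s, pks, spacer_bounds))
  }
  elements <- elements[order(vapply(elements, function(e) e$score,
                                    numeric(1)))]
  list(elements = elements,
       best = if (length(elements) > 0L) elements[[1L]] else NULL)
}
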