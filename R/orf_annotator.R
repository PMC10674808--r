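# ORF discovery and totivirus genome-layout annotation.
#
# Frame convention: frame f in {1,2,3} means codons start at positions p
# with (p - f) mod 3 == 0.  An ORF runs from its AUG to the last base of
# its stop codon; nt_length includes the stop, the protein does not.

# codon -> amino acid, standard genetic code in the RNA alphabet
codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("T", "U", names(tab))
  tab
})

# average residue masses (Da); protein mass = sum(residues) + water
AA_RESIDUE_MASS_DA <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS_DA <- 18.01528

# round half up (R's round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Translate an RNA stretch with the standard genetic code
#'
#' Translation starts at `frame_offset` bases into `rna` and stops at
#' (and excludes) the first stop codon; a trailing partial codon is
#' ignored.
#'
#' @param rna nucleotide string over `{A,C,G,U}`.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @return amino-acid string.
#' @examples
#' translate_rna("AUGAAAUAA")  # "MK"
#' @export
translate_rna <- function(rna, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  if (grepl("[^ACGU]", rna)) {
    stop("translate_rna: sequence contains non-ACGU characters",
         call. = FALSE)
  }
  body <- substring(rna, frame_offset + 1L)
  n_codon <- nchar(body) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(body, starts, starts + 2L)
  aa <- codon_table[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Average molecular mass of a protein in kDa
#'
#' Sum of average residue masses plus one water, reported in kDa.
#' Average (not monoisotopic) masses are used, matching the convention
#' behind "estimated molecular mass" figures for viral proteins.
#'
#' @param protein amino-acid string (standard 20 residues).
#' @param digits decimals kept in the reported value (default 2).
#' @return mass in kDa.
#' @examples
#' protein_mass("G")  # 0.08 kDa (75.07 Da)
#' @export
protein_mass <- function(protein, digits = 2L) {
  if (nchar(protein) == 0L) stop("empty protein", call. = FALSE)
  res <- strsplit(protein, "")[[1]]
  unknown <- setdiff(unique(res), names(AA_RESIDUE_MASS_DA))
  if (length(unknown) > 0L) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  da <- sum(AA_RESIDUE_MASS_DA[res]) + WATER_MASS_DA
  round_half_up(da / 1000, digits)
}

orf_frame <- function(start) ((start - 1L) %% 3L) + 1L

#' Build an ORF annotation from coordinates
#'
#' Validates the coordinate arithmetic (length divisible by 3, ends on a
#' stop codon, no internal stop) and fills in the translated protein and
#' its mass.
#'
#' @param genome a [genome_record()].
#' @param start,end 1-based inclusive bounds of the ORF, including the
#'   stop codon.
#' @return list of class `orf_annotation` with fields `interval`,
#'   `frame`, `start_codon`, `stop_codon`, `nt_length`, `protein`,
#'   `protein_length`, `protein_mass_kda`.
#' @export
orf_annotation <- function(genome, start, end) {
  stopifnot(inherits(genome, "genome_record"))
  iv <- interval(start, end)
  check_interval_in_genome(iv, genome$length)
  nt_len <- interval_length(iv)
  if (nt_len %% 3L != 0L) {
    stop(sprintf("ORF length %d not divisible by 3", nt_len),
         call. = FALSE)
  }
  cds <- substr(genome$sequence, iv$start, iv$end)
  start_codon <- substr(cds, 1L, 3L)
  stop_codon <- substr(cds, nt_len - 2L, nt_len)
  if (!(stop_codon %in% STOP_CODONS)) {
    stop("ORF does not end on a stop codon (found ", stop_codon, ")",
         call. = FALSE)
  }
  protein <- translate_rna(cds)
  if (nchar(protein) != nt_len / 3L - 1L) {
    stop("internal stop codon inside ORF at codon ",
         nchar(protein) + 1L, call. = FALSE)
  }
  structure(
    list(interval = iv, frame = orf_frame(iv$start),
         start_codon = start_codon, stop_codon = stop_codon,
         nt_length = nt_len, protein = protein,
         protein_length = nchar(protein),
         protein_mass_kda = protein_mass(protein)),
    class = "orf_annotation"
  )
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("<orf> %d-%d (frame %d), %d nt, %d aa, %.2f kDa\n",
              x$interval$start, x$interval$end, x$frame, x$nt_length,
              x$protein_length, x$protein_mass_kda))
  invisible(x)
}

#' Find open reading frames
#'
#' Scans the requested frames for maximal AUG-initiated,
#' stop-terminated readings of at least `min_aa` codons (stop
#' excluded).  Within one stop codon only the longest ORF (5'-most AUG)
#' is reported; nested internal AUG starts are suppressed.  Results are
#' sorted by start position.
#'
#' @param genome a [genome_record()].
#' @param min_aa minimum protein length in amino acids (default 100,
#'   suitable for selecting the two long totivirus ORFs at ~4.5 kb
#'   scale).
#' @param strand_policy `"plus"` (default; totivirus coding is reported
#'   on one strand) or `"both"`.
#' @return list of `orf_annotation` objects, possibly empty.
#' @export
find_orfs <- function(genome, min_aa = 100L, strand_policy = c("plus", "both")) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(min_aa >= 1L)
  out <- find_orfs_one_strand(genome, min_aa)
  if (strand_policy == "both") {
    rc <- genome_record(genome$id, revcomp_rna(genome$sequence),
                        description = genome$description)
    rc_orfs <- find_orfs_one_strand(rc, min_aa)
    for (o in rc_orfs) {
      # report minus-strand ORFs in plus coordinates
      s <- genome$length - o$interval$end + 1L
      e <- genome$length - o$interval$start + 1L
      o$interval <- interval(s, e, strand = "-")
      out[[length(out) + 1L]] <- o
    }
  }
  out[order(vapply(out, function(o) o$interval$start, integer(1)))]
}

find_orfs_one_strand <- function(genome, min_aa) {
  seq <- genome$sequence
  n <- genome$length
  if (n < 6L) return(list())
  starts <- seq_len(n - 2L)
  codons <- substring(seq, starts, starts + 2L)
  out <- list()
  for (f in 1:3) {
    idx <- seq(f, n - 2L, by = 3L)
    cf <- codons[idx]
    is_stop <- cf %in% STOP_CODONS
    is_aug <- cf == "AUG"
    open_at <- NA_integer_  # codon index of the 5'-most live AUG
    for (k in seq_along(cf)) {
      if (is_stop[k]) {
        if (!is.na(open_at)) {
          aa_len <- k - open_at  # codons excluding stop
          if (aa_len >= min_aa) {
            out[[length(out) + 1L]] <-
              orf_annotation(genome, idx[open_at], idx[k] + 2L)
          }
          open_at <- NA_integer_
        }
      } else if (is_aug[k] && is.na(open_at)) {
        open_at <- k
      }
    }
  }
  out
}

#' Select the two long ORFs of a totivirus genome
#'
#' Picks the two longest non-overlapping ORFs in distinct frames from a
#' `find_orfs()` result and returns them 5' to 3' (ORF1 = capsid
#' protein, ORF2 = polymerase).
#'
#' @param orfs list of `orf_annotation` objects.
#' @return list with elements `orf1`, `orf2`.
#' @export
select_orf_pair <- function(orfs) {
  if (length(orfs) < 2L) {
    stop("no two long ORFs found", call. = FALSE)
  }
  len <- vapply(orfs, function(o) o$nt_length, integer(1))
  ord <- order(-len, vapply(orfs, function(o) o$interval$start, integer(1)))
  a <- orfs[[ord[1L]]]
  for (j in ord[-1L]) {
    b <- orfs[[j]]
    disjoint <- b$interval$start > a$interval$end ||
      b$interval$end < a$interval$start
    if (disjoint && b$frame != a$frame) {
      pair <- if (a$interval$start < b$interval$start) list(a, b) else list(b, a)
      return(list(orf1 = pair[[1L]], orf2 = pair[[2L]]))
    }
  }
  stop("no two long ORFs found in distinct frames without overlap",
       call. = FALSE)
}

#' Annotate the layout of a totivirus genome
#'
#' Computes the 5' UTR, intergenic region and 3' UTR implied by the two
#' ORFs, plus the genome GC content.  Segment lengths satisfy
#' `utr5 + orf1 + intergenic + orf2 + utr3 == genome_length` when the
#' ORFs do not overlap.
#'
#' @param genome a [genome_record()].
#' @param orf1,orf2 `orf_annotation` objects, 5' to 3'.
#' @param allow_overlap permit `orf2` to start before `orf1` ends
#'   (overlapping ORFs occur in some totiviruses); the intergenic
#'   interval is then `NULL`.
#' @return list of class `genome_annotation`.
#' @examples
#' \dontrun{
#' ann <- annotate_genome(g, orf1, orf2)
#' interval_length(ann$utr5)
#' }
#' @export
annotate_genome <- function(genome, orf1, orf2, allow_overlap = FALSE) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(orf1, "orf_annotation"),
            inherits(orf2, "orf_annotation"))
  check_interval_in_genome(orf2$interval, genome$length)
  if (orf2$interval$start <= orf1$interval$end && !allow_overlap) {
    stop("ORFs overlap; pass allow_overlap = TRUE if intended",
         call. = FALSE)
  }
  n <- genome$length
  utr5 <- if (orf1$interval$start > 1L) {
    interval(1L, orf1$interval$start - 1L)
  } else NULL
  utr3 <- if (orf2$interval$end < n) {
    interval(orf2$interval$end + 1L, n)
  } else NULL
  ir <- if (orf2$interval$start > orf1$interval$end + 1L) {
    interval(orf1$interval$end + 1L, orf2$interval$start - 1L)
  } else NULL
  gc <- gc_percent(genome$sequence)
  structure(
    list(genome_id = genome$id, genome_length = n, gc_percent = gc,
         utr5 = utr5, orf1 = orf1, intergenic = ir, orf2 = orf2,
         utr3 = utr3),
    class = "genome_annotation"
  )
}

#' GC content of a sequence in percent
#'
#' @param seq nucleotide string.
#' @param digits decimals reported (default 1, half-up).
#' @return percent G+C.
#' @export
gc_percent <- function(seq, digits = 1L) {
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  round_half_up(100 * gc / n, digits)
}

#' @export
print.genome_annotation <- function(x, ...) {
  seg <- function(iv) if (is.null(iv)) "-" else
    sprintf("%d-%d (%d nt)", iv$start, iv$end, interval_length(iv))
  cat(sprintf("<genome_annotation> %s, %d nt, GC %.1f%%\n",
              x$genome_id, x$genome_length, x$gc_percent))
  cat("  5' UTR     ", seg(x$utr5), "\n")
  cat(sprintf("  ORF1       %d-%d (frame %d, %d nt, %d aa, %.2f kDa)\n",
              x$orf1$interval$start, x$orf1$interval$end, x$orf1$frame,
              x$orf1$nt_length, x$orf1$protein_length,
              x$orf1$protein_mass_kda))
  cat("  intergenic ", seg(x$intergenic), "\n")
  cat(sprintf("  ORF2       %d-%d (frame %d, %d nt, %d aa, %.2f kDa)\n",
              x$orf2$interval$start, x$orf2$interval$end, x$orf2$frame,
              x$orf2$nt_length, x$orf2$protein_length,
              x$orf2$protein_mass_kda))
  cat("  3' UTR     ", seg(x$utr3), "\n")
  invisible(x)
}

#' One-call genome annotation
#'
#' `find_orfs()` + `select_orf_pair()` + `annotate_genome()`.
#'
#' @inheritParams find_orfs
#' @return a `genome_annotation`.
#' @export
annotate <- function(genome, min_aa = 100L,
                     strand_policy = c("plus", "both")) {
  orfs <- find_orfs(genome, min_aa = min_aa,
                    strand_policy = match.arg(strand_policy))
  pair <- select_orf_pair(orfs)
  annotate_genome(genome, pair$orf1, pair$orf2)
}

#' Summarize an annotation as a table
#'
#' @param annotation a `genome_annotation`.
#' @return data.frame with one row per ORF (columns: genome_id, length,
#'   gc_percent, orf, start, end, frame, nt_len, aa_len, mass_kda).
#' @export
annotation_summary <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  row <- function(name, o) data.frame(
    genome_id = annotation$genome_id, length = annotation$genome_length,
    gc_percent = annotation$gc_percent, orf = name,
    start = o$interval$start, end = o$interval$end, frame = o$frame,
    nt_len = o$nt_length, aa_len = o$protein_length,
    mass_kda = o$protein_mass_kda, stringsAsFactors = FALSE)
  rbind(row("orf1", annotation$orf1), row("orf2", annotation$orf2))
}
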