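# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations of each contract; they never call
# the implementation paths they check.

oracle_bases <- c("A", "C", "G", "U")

random_rna <- function(n) {
  paste(sample(oracle_bases, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# --- ORF enumeration --------------------------------------------------

# every (start, frame) pair is tested independently; the
# longest-per-stop rule is applied afterwards by grouping on the stop
oracle_find_orfs <- function(seq, min_aa) {
  stops <- c("UAA", "UAG", "UGA")
  n <- nchar(seq)
  found <- list()
  for (start in seq_len(n - 2L)) {
    if (substr(seq, start, start + 2L) != "AUG") next
    p <- start
    repeat {
      if (p + 2L > n) break  # ran off the end: not stop-terminated
      codon <- substr(seq, p, p + 2L)
      if (codon %in% stops) {
        aa_len <- (p - start) %/% 3L
        if (aa_len >= min_aa) {
          found[[length(found) + 1L]] <- c(start = start, end = p + 2L)
        }
        break
      }
      p <- p + 3L
    }
  }
  if (length(found) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  df <- as.data.frame(do.call(rbind, found))
  # longest per stop: keep the smallest start for each end
  df <- df[order(df$end, df$start), ]
  df <- df[!duplicated(df$end), ]
  df[order(df$start), , drop = FALSE]
}

# --- slippery heptamer grammar ----------------------------------------

oracle_slippery <- function(hep) {
  if (nchar(hep) != 7L) return(FALSE)
  b <- strsplit(hep, "")[[1]]
  x_ok <- b[1] %in% c("A", "C", "G", "U") && b[1] == b[2] && b[1] == b[3]
  y_ok <- b[4] %in% c("A", "U") && b[4] == b[5] && b[4] == b[6]
  z_ok <- b[7] %in% c("A", "C", "U")
  x_ok && y_ok && z_ok
}

# --- Hamming read mapping ---------------------------------------------

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

# minimum-mismatch placement over all offsets of both strands; ties:
# plus strand first, then smallest offset
oracle_map <- function(target, read, max_mm = 1L) {
  tc <- strsplit(target, "")[[1]]
  scan <- function(rd) {
    rc <- strsplit(rd, "")[[1]]
    m <- length(rc)
    noff <- length(tc) - m + 1L
    if (noff < 1L) return(c(mm = max_mm + 1L, pos = NA_integer_))
    mism <- integer(noff)
    for (k in seq_len(m)) {
      mism <- mism + (tc[k:(k + noff - 1L)] != rc[k])
    }
    c(mm = min(mism), pos = which.min(mism))
  }
  plus <- scan(read)
  minus <- scan(oracle_revcomp(read))
  if (plus["mm"] <= minus["mm"]) {
    best <- plus; strand <- "+"
  } else {
    best <- minus; strand <- "-"
  }
  if (best["mm"] > max_mm) {
    list(mapped = FALSE, position = NA_integer_, strand = NA_character_,
         mismatches = NA_integer_)
  } else {
    list(mapped = TRUE, position = unname(best["pos"]), strand = strand,
         mismatches = unname(best["mm"]))
  }
}

# --- global affine alignment by exhaustive path enumeration ------------

# recursion over the three moves with affine gap accounting; no
# memoization, no DP -- usable only for short strings
oracle_align_score <- function(q, r, sub, gap_open, gap_ext) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  rec2 <- function(i, j, prev) {
    if (i > length(qc) && j > length(rc)) return(0)
    best <- -Inf
    if (i <= length(qc) && j <= length(rc)) {
      best <- max(best, sub[qc[i], rc[j]] + rec2(i + 1L, j + 1L, "M"))
    }
    if (i <= length(qc)) {
      cost <- if (prev == "X") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec2(i + 1L, j, "X"))
    }
    if (j <= length(rc)) {
      cost <- if (prev == "Y") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec2(i, j + 1L, "Y"))
    }
    best
  }
  rec2(1L, 1L, "start")
}

# --- pseudoknot energy re-summation -----------------------------------

# independent constants table and re-summation from the pair lists
oracle_pk_energy <- function(pk, genome_seq) {
  chars <- strsplit(genome_seq, "")[[1]]
  val <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = , CG = -3.0, AU = , UA = -2.0, GU = , UG = -1.0,
           stop("non-pairable pair in stem: ", key))
  }
  s <- 0
  for (stem in list(pk$stem1, pk$stem2)) {
    for (row in seq_len(nrow(stem))) {
      s <- s + val(chars[stem[row, 1]], chars[stem[row, 2]])
    }
  }
  s + 0.2 * sum(pk$loop_lengths) + 7.0
}
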