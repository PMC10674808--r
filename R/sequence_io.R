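# Sequence containers and standard-format IO.
#
# Conventions used throughout the package:
#   * coordinates are 1-based inclusive (GFF3-style), plus strand unless
#     stated otherwise;
#   * the internal alphabet is RNA {A,C,G,U}; T is converted to U on
#     input.  Ambiguity codes are rejected by default.

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases, converts T to U and validates the alphabet.  With
#' `allow_ambiguity = TRUE` any IUPAC ambiguity code is mapped to the
#' sentinel `N`, which is excluded from base pairing and always counts
#' as a mismatch during read mapping.
#'
#' @param x character scalar, nucleotide sequence (DNA or RNA).
#' @param allow_ambiguity keep ambiguity codes as `N` instead of
#'   raising an error.
#' @return character scalar over `{A,C,G,U}` (plus `N` when permitted).
#' @export
normalize_rna <- function(x, allow_ambiguity = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "u", tolower(x))
  x <- toupper(x)
  bad <- gsub("[ACGU]", "", x)
  if (nzchar(bad)) {
    if (!allow_ambiguity) {
      stop("sequence contains non-ACGU characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
           " (use allow_ambiguity = TRUE to mask them as N)",
           call. = FALSE)
    }
    iupac <- "RYSWKMBDHVN"
    chars <- unique(strsplit(bad, "")[[1]])
    unknown <- setdiff(chars, strsplit(iupac, "")[[1]])
    if (length(unknown) > 0L) {
      stop("sequence contains non-nucleotide characters: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    x <- chartr(iupac, strrep("N", nchar(iupac)), x)
  }
  x
}

#' Reverse complement in the RNA alphabet
#'
#' A<->U, G<->C; the sentinel `N` maps to itself.  G.U wobble plays no
#' role here: reverse complementation is exact.
#'
#' @param x character scalar over `{A,C,G,U,N}`.
#' @return character scalar, the reverse complement.
#' @export
revcomp_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGUN", "UGCAN", x), "")[[1]]), collapse = "")
}

#' Construct a genome record
#'
#' The unit every annotation operation works on: an identified
#' nucleotide sequence normalized to the RNA alphabet.
#'
#' @param id sequence identifier (must be non-empty).
#' @param sequence nucleotide string; DNA is converted to RNA.
#' @param description optional free-text description.
#' @param allow_ambiguity see [normalize_rna()].
#' @return an object of class `genome_record` with fields `id`,
#'   `description`, `sequence` and `length`.
#' @examples
#' g <- genome_record("g1", "ATGC")
#' g$sequence  # "AUGC"
#' @export
genome_record <- function(id, sequence, description = "",
                          allow_ambiguity = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence, allow_ambiguity = allow_ambiguity)
  structure(
    list(id = id, description = description, sequence = sequence,
         length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  (%d nt)\n", x$id, x$length))
  prefix <- substr(x$sequence, 1, 60)
  cat(" ", prefix, if (x$length > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Parsing is delegated to Biostrings; sequences are normalized to the
#' RNA alphabet (T becomes U).  Record order is preserved.
#'
#' @param path FASTA file (multi-record allowed).
#' @param allow_ambiguity see [normalize_rna()].
#' @return list of [genome_record()] objects.
#' @export
read_fasta <- function(path, allow_ambiguity = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- genome_record(ids[i], as.character(set[[i]]),
                              description = descs[i],
                              allow_ambiguity = allow_ambiguity)
  }
  out
}

#' Write genome records to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records list of [genome_record()] objects (a single record is
#'   accepted too).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  descs <- vapply(records, function(r) r$description, character(1))
  nm <- ifelse(nzchar(descs), paste(ids, descs), ids)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read small-RNA reads from FASTQ
#'
#' A strict 4-line-per-record reader: it validates record structure and
#' reports the index of the first malformed record, which the pipeline
#' relies on to catch truncated downloads early.  Qualities are parsed
#' and discarded (mapping is quality-blind).
#'
#' @param path FASTQ file (Sanger quality; uncompressed).
#' @param allow_ambiguity see [normalize_rna()].
#' @return an `srna_set`: a data.frame with columns `id`, `sequence`,
#'   `length`.
#' @export
read_fastq <- function(path, allow_ambiguity = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTQ file: ", path, call. = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record index ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) == 0L | nchar(qual) != nchar(seqs))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at record index ", bad[1L], call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  seqs <- vapply(seqs, normalize_rna, character(1),
                 allow_ambiguity = allow_ambiguity, USE.NAMES = FALSE)
  srna_set(ids, seqs)
}

#' Build a small-RNA read set
#'
#' @param id character vector of read identifiers.
#' @param sequence character vector of RNA sequences (already
#'   normalized).
#' @return data.frame of class `srna_set` with columns `id`, `sequence`,
#'   `length`.
#' @export
srna_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  out <- data.frame(id = as.character(id),
                    sequence = as.character(sequence),
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  if (any(out$length < 1L)) stop("zero-length read in set", call. = FALSE)
  class(out) <- c("srna_set", "data.frame")
  out
}

#' Write a read set to FASTQ with uniform placeholder qualities
#'
#' @param reads an `srna_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  rec <- paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                strrep("I", reads$length))
  writeLines(rec, con)
  invisible(path)
}

#' Write a genome annotation to GFF3
#'
#' Emits `five_prime_UTR`, one `CDS` per ORF, the intergenic region as a
#' `biological_region`, and `three_prime_UTR`, in 1-based inclusive
#' coordinates (no conversion is needed: the package convention matches
#' GFF3).  Zero-length segments (for example a missing UTR) are
#' omitted.  Writing is delegated to rtracklayer.
#'
#' @param annotation a `genome_annotation` (see [annotate_genome()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(annotation, path) {
  feats <- annotation_features(annotation)
  if (nrow(feats) > 1L) {
    o <- order(feats$start)
    fs <- feats[o, , drop = FALSE]
    if (any(fs$start[-1L] <= fs$end[-nrow(fs)])) {
      stop("overlapping features in annotation; refusing to write GFF3",
           call. = FALSE)
    }
  }
  if (nrow(feats) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+",
    type = feats$type,
    source = "totikit",
    ID = feats$id,
    # complete ORFs start in-frame
    phase = ifelse(feats$type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Flatten an annotation into a feature table (start/end/type/id),
# dropping zero-length segments.
annotation_features <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  rows <- list()
  add <- function(iv, type, id) {
    if (!is.null(iv) && iv$end >= iv$start) {
      rows[[length(rows) + 1L]] <<- data.frame(
        start = iv$start, end = iv$end, type = type, id = id,
        stringsAsFactors = FALSE)
    }
  }
  add(annotation$utr5, "five_prime_UTR", "utr5")
  if (!is.null(annotation$orf1)) {
    add(annotation$orf1$interval, "CDS", "orf1")
  }
  add(annotation$intergenic, "biological_region", "intergenic")
  if (!is.null(annotation$orf2)) {
    add(annotation$orf2$interval, "CDS", "orf2")
  }
  add(annotation$utr3, "three_prime_UTR", "utr3")
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      type = character(), id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Construct a 1-based inclusive interval
#'
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return list of class `interval`.
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L,
            strand %in% c("+", "-"))
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop(sprintf("invalid interval [%s, %s]", start, end), call. = FALSE)
  }
  structure(list(start = start, end = end, strand = strand),
            class = "interval")
}

interval_length <- function(iv) iv$end - iv$start + 1L

check_interval_in_genome <- function(iv, genome_length) {
  if (iv$end > genome_length) {
    stop(sprintf("interval [%d, %d] exceeds genome length %d",
                 iv$start, iv$end, genome_length), call. = FALSE)
  }
  invisible(TRUE)
}
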