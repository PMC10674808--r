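# One-shot pipeline: annotate -> prf-scan -> motif-scan -> srna-profile,
# driven by a validated config, with per-stage artifacts and a single
# deterministic JSON report.

PIPELINE_PARAM_DEFAULTS <- list(
  min_aa = 100L,
  max_upstream = 200L,
  spacer_bounds = c(1L, 30L),
  max_mm = 1L,
  window_width = 100L
)

#' Build and validate a pipeline run configuration
#'
#' @param genome_fasta path to the viral genome FASTA (required).
#' @param reads_fastq optional small-RNA FASTQ; enables the profiling
#'   stage.
#' @param host_fasta optional host reference FASTA; profiled alongside
#'   the viral targets as the mapping control.
#' @param out_dir output directory (created if missing).
#' @param params named list overriding entries of the stage-parameter
#'   defaults (`min_aa`, `max_upstream`, `spacer_bounds`, `max_mm`,
#'   `window_width`); unknown keys are rejected.
#' @param seed integer seed recorded in the report (the analysis stages
#'   are deterministic; the seed matters only when inputs were
#'   simulated).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(genome_fasta, reads_fastq = NULL,
                       host_fasta = NULL, out_dir = tempfile("totikit_"),
                       params = list(), seed = 1L) {
  if (!file.exists(genome_fasta)) {
    stop("config error: genome_fasta does not exist: ", genome_fasta,
         call. = FALSE)
  }
  unknown <- setdiff(names(params), names(PIPELINE_PARAM_DEFAULTS))
  if (length(unknown) > 0L) {
    stop("config error: unknown parameter key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (pth in c(reads_fastq, host_fasta)) {
    if (!is.null(pth) && !file.exists(pth)) {
      stop("config error: input does not exist: ", pth, call. = FALSE)
    }
  }
  structure(
    list(genome_fasta = genome_fasta, reads_fastq = reads_fastq,
         host_fasta = host_fasta, out_dir = out_dir,
         params = modifyList(PIPELINE_PARAM_DEFAULTS, params),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Accepts the same keys as [run_config()] (with `params` as a nested
#' object); unknown top-level keys are rejected.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: no such config file: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("genome_fasta", "reads_fastq", "host_fasta", "out_dir",
             "params", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$params)) args$params <- as.list(args$params)
  do.call(run_config, args)
}

#' Run the full characterization pipeline
#'
#' Stages run in order (annotate, prf-scan, motif-scan, and, when reads
#' are supplied, srna-profile); per-stage artifacts (GFF3, TSV, JSON)
#' are written under `config$out_dir`, followed by a consolidated
#' `report.json`.  Identical inputs and config yield byte-identical
#' reports.  A stage failure marks the stage in the report, skips
#' downstream stages and raises a condition of class
#' `totikit_stage_error`.
#'
#' @param config a [run_config()].
#' @return the report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  report <- list(
    provenance = list(package = "totikit",
                      version = as.character(utils::packageVersion("totikit")),
                      seed = config$seed,
                      config = config[c("genome_fasta", "reads_fastq",
                                        "host_fasta", "params")]),
    stages = list(), genomes = list(), profiles = list())

  fail_stage <- function(stage, e) {
    report$stages[[stage]] <<- list(status = "failed",
                                    message = conditionMessage(e))
    write_report(report, config$out_dir)
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("totikit_stage_error", "error")))
  }

  # -- annotate ---------------------------------------------------------
  genomes <- read_fasta(config$genome_fasta)
  annotated <- tryCatch(
    lapply(genomes, annotate, min_aa = p$min_aa),
    error = function(e) fail_stage("annotate", e))
  report$stages$annotate <- list(status = "ok")
  summaries <- do.call(rbind, lapply(annotated, annotation_summary))
  write.table(summaries, file.path(config$out_dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(annotated)) {
    write_gff3(annotated[[i]],
               file.path(config$out_dir,
                         paste0(annotated[[i]]$genome_id, ".gff3")))
  }

  # -- prf-scan ---------------------------------------------------------
  prf <- tryCatch(
    lapply(seq_along(genomes), function(i) {
      ann <- annotated[[i]]
      scan <- prf_scan(genomes[[i]], ann$orf1, ann$orf2,
                       max_upstream = p$max_upstream,
                       spacer_bounds = p$spacer_bounds,
                       window_width = p$window_width)
      best <- scan$best
      fusion <- if (!is.null(best)) {
        tryCatch(fusion_protein(genomes[[i]], ann$orf1, best$slippery,
                                ann$orf2),
                 error = function(e) NULL)
      }
      list(scan = scan, fusion = fusion)
    }),
    error = function(e) fail_stage("prf_scan", e))
  report$stages$prf_scan <- list(status = "ok")

  # -- motif-scan -------------------------------------------------------
  motifs <- tryCatch(
    lapply(annotated, function(ann) {
      list(cp = motif_scan(ann$orf1$protein, "cp"),
           rdrp = motif_scan(ann$orf2$protein, "rdrp"))
    }),
    error = function(e) fail_stage("motif_scan", e))
  report$stages$motif_scan <- list(status = "ok")

  for (i in seq_along(genomes)) {
    ann <- annotated[[i]]
    best <- prf[[i]]$scan$best
    fusion <- prf[[i]]$fusion
    report$genomes[[ann$genome_id]] <- list(
      length = ann$genome_length, gc_percent = ann$gc_percent,
      utr5 = iv_or_null(ann$utr5), orf1 = orf_report(ann$orf1),
      intergenic = iv_or_null(ann$intergenic),
      orf2 = orf_report(ann$orf2), utr3 = iv_or_null(ann$utr3),
      prf = if (is.null(best)) NULL else list(
        heptamer = best$slippery$heptamer,
        slippery = c(best$slippery$interval$start,
                     best$slippery$interval$end),
        spacer = best$spacer_length,
        pseudoknot_span = c(best$pseudoknot$span$start,
                            best$pseudoknot$span$end),
        efe_kcal_mol = best$pseudoknot$efe_kcal_mol),
      fusion = if (is.null(fusion)) NULL else list(
        pre_shift_codons = fusion$pre_shift_codons,
        post_shift_codons = fusion$post_shift_codons,
        protein_length = fusion$protein_length,
        mass_kda = fusion$mass_kda),
      motifs = list(
        cp = motifs[[i]]$cp,
        rdrp = motifs[[i]]$rdrp))
  }

  # -- srna-profile -----------------------------------------------------
  if (!is.null(config$reads_fastq)) {
    prof <- tryCatch({
      reads <- read_fastq(config$reads_fastq, allow_ambiguity = TRUE)
      targets <- genomes
      if (!is.null(config$host_fasta)) {
        targets <- c(targets, read_fasta(config$host_fasta,
                                         allow_ambiguity = TRUE))
      }
      build_profile(reads, targets, max_mm = p$max_mm)
    }, error = function(e) fail_stage("srna_profile", e))
    report$stages$srna_profile <- list(status = "ok")
    for (tid in names(prof)) {
      tab <- prof[[tid]]
      write.table(tab, file.path(config$out_dir,
                                 paste0("profile_", tid, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cls <- classify_lengths(tab)
      report$profiles[[tid]] <- list(
        total = sum(tab$total),
        perfect_match = sum(tab$perfect_match),
        one_mismatch = sum(tab$one_mismatch),
        fraction_perfect =
          if (sum(tab$total) > 0L) fraction_perfect(tab) else NA,
        class_counts = as.list(cls$counts),
        modal_length = cls$modal_length)
      write.table(cls$histogram,
                  file.path(config$out_dir,
                            paste0("histogram_", tid, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  write_report(report, config$out_dir)
  invisible(report)
}

iv_or_null <- function(iv) {
  if (is.null(iv)) NULL else c(iv$start, iv$end)
}

orf_report <- function(o) {
  list(start = o$interval$start, end = o$interval$end, frame = o$frame,
       nt_length = o$nt_length, protein_length = o$protein_length,
       mass_kda = o$protein_mass_kda)
}

write_report <- function(report, out_dir) {
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}
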