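#' Pipeline run configuration
#'
#' Collects every tunable of the per-sample pipeline with its default:
#' the three molecule gap parameters, the five-split-molecule support
#' rule, the copy-number threshold for high-level amplification, the 10%
#' variant-allele-fraction floor, and mapping-quality / clustering
#' settings.
#'
#' @param d_values molecule gap parameters in bp.
#' @param min_support minimum barcoded split molecules per SV call.
#' @param window split-molecule matching window; `NULL` = use each `d`.
#' @param merge_tol cross-d merge tolerance (bp).
#' @param min_shared shared barcodes required to phase two SV calls.
#' @param cn_threshold high-amplification copy-number threshold.
#' @param ploidy_control control-region ploidy (1 = haploid chrX).
#' @param min_vaf minimum SNV variant allele fraction.
#' @param min_mapq minimum alignment mapping quality.
#' @param max_insert maximum proper-pair span (bp).
#' @param cluster_tol discordant-pair clustering tolerance (bp).
#' @param min_pairs minimum discordant pairs per candidate.
#' @param min_reads_per_molecule minimum reads per reconstructed molecule.
#' @param seed integer seed for any simulation step driven by the config.
#' @return list of class `run_config`.
#' @export
run_config <- function(d_values = c(1000, 5000, 10000), min_support = 5L,
                       window = NULL, merge_tol = 1000, min_shared = 1L,
                       cn_threshold = 8, ploidy_control = 1,
                       min_vaf = 0.10, min_mapq = 30, max_insert = 2000,
                       cluster_tol = 500, min_pairs = 2L,
                       min_reads_per_molecule = 2L, seed = 1L) {
  cfg <- as.list(environment())
  if (!length(cfg$d_values) || any(cfg$d_values <= 0))
    stop("d_values must be positive and non-empty")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("linkphase run configuration:\n")
  for (f in names(x))
    cat(sprintf("  %-24s %s\n", f,
                paste(x[[f]] %||% "(default)", collapse = ", ")))
  invisible(x)
}

stage_log <- function(stage, ...) {
  message(sprintf("[linkphase] %s: %s", stage, sprintf(...)))
}

#' Run the full per-sample pipeline
#'
#' Orchestrates molecule reconstruction, SV calling across the configured
#' gap parameters, barcode phasing, targeted copy-number estimation and
#' SNV filtering for one sample, optionally writing every artifact
#' (BEDPE, network JSON, CN TSV, filtered VCF, summary TSV) to `outdir`.
#' The run is deterministic given its inputs and configuration; one log
#' line per stage reports record counts.
#'
#' @param config a [run_config()].
#' @param alignments alignment table, or path to a TSV/BAM readable by
#'   [read_alignments()].
#' @param targets target panel data.frame (see [read_target_bed()]) or
#'   path to a BED; rows with role `target` define the copy-number target
#'   (the first target label is used), rows with role `control` the
#'   denominator.
#' @param snv_vcf optional path to an SNV VCF (or a data.frame of calls).
#' @param annotation optional oncogenicity annotation table or TSV path;
#'   required when `snv_vcf` is given.
#' @param sample_id sample label used in outputs.
#' @param outdir optional output directory for artifact files.
#' @return list of class `sample_summary` with the per-sample flags
#'   (`cn`, `high_cn`, `has_sv`, `has_phased_sv`, `n_svs`, `n_phased`,
#'   `n_snvs_kept`) plus the underlying `calls`, `network`, `cn_estimate`
#'   and `snvs_kept` objects.
#' @export
run_sample <- function(config, alignments, targets, snv_vcf = NULL,
                       annotation = NULL, sample_id = "sample",
                       outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  reads <- if (is.character(alignments))
    read_alignments(alignments, min_mapq = config$min_mapq)
  else as_reads_table(alignments)
  stage_log("alignments", "%d records retained", nrow(reads))
  if (is.character(targets)) targets <- read_target_bed(targets)
  targets <- as.data.frame(targets)

  calls <- call_svs(reads, d_values = config$d_values,
                    w = config$window, min_support = config$min_support,
                    max_insert = config$max_insert,
                    cluster_tol = config$cluster_tol,
                    min_pairs = config$min_pairs,
                    merge_tol = config$merge_tol,
                    min_reads_per_molecule = config$min_reads_per_molecule)
  stage_log("call-sv", "%d call(s) with >= %d split molecules",
            nrow(calls), config$min_support)

  network <- phase_svs(calls, min_shared = config$min_shared)
  stage_log("phase", "%d component(s), %d edge(s)",
            length(network$components), nrow(network$edges))

  target_rows <- targets[targets$role == "target", , drop = FALSE]
  control_rows <- targets[targets$role == "control", , drop = FALSE]
  if (!nrow(target_rows) || !nrow(control_rows))
    stop("stage cnv: targets must contain both 'target' and 'control' rows")
  cn <- estimate_copy_number(reads, target_rows[1L, ], control_rows,
                             ploidy_control = config$ploidy_control,
                             high_cn_threshold = config$cn_threshold)
  stage_log("cnv", "%s cn = %.2f (high: %s)", cn$region, cn$cn, cn$high_cn)

  snvs_kept <- NULL
  n_snvs_kept <- 0L
  if (!is.null(snv_vcf)) {
    if (is.null(annotation))
      stop("stage filter-snv: annotation table required with snv_vcf")
    snv_calls <- if (is.character(snv_vcf)) read_snv_vcf(snv_vcf)
    else as.data.frame(snv_vcf)
    if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
    snvs_kept <- filter_snvs(snv_calls, annotation,
                             min_vaf = config$min_vaf)
    n_snvs_kept <- nrow(snvs_kept)
    stage_log("filter-snv", "%d of %d call(s) kept", n_snvs_kept,
              nrow(snv_calls))
  }

  flags <- summarize_phasing(network, cn)
  summary <- structure(c(list(sample = sample_id), flags,
                         list(n_snvs_kept = n_snvs_kept, calls = calls,
                              network = network, cn_estimate = cn,
                              snvs_kept = snvs_kept)),
                       class = "sample_summary")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(ext) file.path(outdir, paste0(sample_id, ext))
    write_sv_bedpe(calls, p(".sv.bedpe"))
    write_phase_network_json(network, p(".network.json"))
    write_cn_tsv(data.frame(sample = sample_id, region = cn$region,
                            cn = cn$cn, high_cn = cn$high_cn), p(".cn.tsv"))
    if (!is.null(snvs_kept)) write_snv_vcf(snvs_kept, p(".snv.filtered.vcf"))
    fwrite(summary_row(summary), p(".summary.tsv"), sep = "\t")
    stage_log("artifacts", "written to %s", outdir)
  }
  summary
}

summary_row <- function(s) {
  data.table(sample = s$sample, cn = s$cn, high_cn = s$high_cn,
             has_sv = s$has_sv, has_phased_sv = s$has_phased_sv,
             n_svs = s$n_svs, n_phased = s$n_phased,
             max_component = s$max_component, n_snvs_kept = s$n_snvs_kept)
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("Sample %s: cn = %.2f (high: %s), %d SV(s), %d phased, %d SNV(s) kept\n",
              x$sample, x$cn, x$high_cn, x$n_svs, x$n_phased, x$n_snvs_kept))
  invisible(x)
}

#' Aggregate per-sample summaries into a cohort report
#'
#' Builds the oncoprint-style per-sample table, the cohort alteration
#' frequencies, and both Fisher's exact enrichment tests (any SV, and
#' phased SV, versus high-level amplification).
#'
#' @param summaries list of [run_sample()] results (or equivalent lists
#'   with fields `sample`, `cn`, `high_cn`, `has_sv`, `has_phased_sv`,
#'   `n_snvs_kept`).
#' @param cn_threshold copy-number threshold for the tests (default 8);
#'   all samples must have been flagged at this same threshold.
#' @param outdir optional directory for `cohort.oncoprint.tsv` and
#'   `cohort.stats.json`.
#' @return list of class `cohort_report` with `oncoprint`, `frequencies`
#'   and `tests` (per feature: contingency table and p-value).
#' @export
run_cohort <- function(summaries, cn_threshold = 8, outdir = NULL) {
  if (length(summaries) < 2L) stop("need at least two samples")
  thr <- unique(unlist(lapply(summaries, function(s)
    s$cn_estimate$high_cn_threshold %||% cn_threshold)))
  if (length(thr) > 1L)
    stop("samples were flagged at different cn thresholds: ",
         paste(thr, collapse = ", "))
  rows <- rbindlist(lapply(summaries, function(s) {
    data.table(sample = s$sample, cn = s$cn,
               high_cn = isTRUE(s$high_cn) || flag_high_cn(s$cn, cn_threshold),
               has_sv = isTRUE(s$has_sv),
               has_phased_sv = isTRUE(s$has_phased_sv),
               n_svs = s$n_svs %||% 0L,
               n_snvs_kept = s$n_snvs_kept %||% 0L)
  }))
  tests <- lapply(c(has_sv = "has_sv", has_phased_sv = "has_phased_sv"),
                  function(f) {
                    tab <- build_contingency(rows, f, cn_threshold)
                    list(feature = f, table = tab, cn_threshold = cn_threshold,
                         p = fisher_exact_two_sided(tab))
                  })
  report <- structure(list(oncoprint = as.data.frame(rows),
                           frequencies = cohort_summary(rows, cn_threshold),
                           tests = tests, cn_threshold = cn_threshold),
                      class = "cohort_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fwrite(rows, file.path(outdir, "cohort.oncoprint.tsv"), sep = "\t")
    jsonlite::write_json(
      list(frequencies = report$frequencies,
           tests = lapply(tests, function(t) list(
             feature = t$feature, table = as.vector(t$table),
             cn_threshold = t$cn_threshold, p = t$p))),
      file.path(outdir, "cohort.stats.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d samples\n", nrow(x$oncoprint)))
  print(x$frequencies, row.names = FALSE)
  for (t in x$tests)
    cat(sprintf(
      "  %s vs cn >= %g: %d/%d versus %d/%d, Fisher's exact P = %.2g\n",
      t$feature, t$cn_threshold, t$table[1, 1],
      sum(t$table[1, ]), t$table[2, 1], sum(t$table[2, ]), t$p))
  invisible(x)
}
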