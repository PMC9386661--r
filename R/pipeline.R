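#' Run the duplex consensus calling pipeline end to end
#'
#' Orchestrates the workflow stages in order: read acquisition (simulated
#' library or FASTQ input), pre-processing (padding, homopolymer filter,
#' tag/anchor parsing), placement, tag-family grouping, SSCS assembly, DCS
#' assembly, alignment filters, and SNV/indel calling; optionally also
#' copy-number calls over a panel and the SNP identity fingerprint. Returns
#' a machine-readable report with stage-by-stage record counts, which are
#' mutually consistent: every read pair is accounted for by exactly one of
#' kept/dropped, and every SSCS by exactly one of paired/unpaired/ambiguous.
#'
#' @param sim a [sim_config()] object to simulate the input library, or
#'   `NULL` to read FASTQ.
#' @param fastq_r1,fastq_r2 paired FASTQ paths (ignored when `sim` given).
#' @param reference named character vector of contigs; defaults to the
#'   simulation's reference.
#' @param params pipeline parameters.
#' @param anchor expected anchor sequence; defaults to the simulation's.
#' @param placement `"truth"` (simulator ground truth; only with `sim`) or
#'   `"naive"` (built-in exact-match placement for synthetic references).
#' @param panel optional `GRanges` panel (see [read_panel_bed()]) for
#'   copy-number calls.
#' @param identity_loci optional locus table for [snp_fingerprint()].
#' @param outdir optional output directory; when given, the VCF, drop logs,
#'   consensus SAM and JSON report are written there.
#' @return list of class `run_report` with `counts`, `calls`, `cnv`,
#'   `fingerprint`, `seed` and `outputs`.
#' @export
run_pipeline <- function(sim = NULL, fastq_r1 = NULL, fastq_r2 = NULL,
                         reference = NULL, params = pipeline_params(),
                         anchor = NULL, placement = c("truth", "naive"),
                         panel = NULL, identity_loci = NULL, outdir = NULL) {
  placement <- match.arg(placement)
  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    lib <- simulate_duplex_library(sim)
    r1 <- lib$r1; r2 <- lib$r2; truth <- lib$truth
    if (is.null(reference)) reference <- sim$reference
    if (is.null(anchor)) anchor <- sim$anchor
    seed <- sim$seed
  } else {
    if (is.null(fastq_r1) || is.null(fastq_r2))
      stop("run_pipeline: provide either `sim` or both FASTQ paths")
    if (is.null(reference))
      stop("run_pipeline: `reference` is required with FASTQ input")
    if (is.null(anchor))
      stop("run_pipeline: `anchor` is required with FASTQ input")
    r1 <- read_fastq(fastq_r1); r2 <- read_fastq(fastq_r2)
    seed <- NA_integer_
  }
  if (placement == "truth" && is.null(truth))
    stop("run_pipeline: truth placement requires a simulated library")

  pre <- preprocess_pairs(r1, r2, anchor = anchor, params = params)
  placed <- if (placement == "truth")
    placements_from_truth(pre$kept, truth, params)
  else place_reads_naive(pre$kept, reference, params)
  grouped <- group_families(placed$reads, params)
  sscs <- build_all_sscs(grouped, params)
  duplex <- pair_and_build_dcs(sscs$sscs, params)
  aligned <- align_dcs(duplex$dcs, reference)
  filt <- filter_dcs(aligned, reference, params)
  snvs <- call_snvs(filt$retained, reference, params)
  indels <- call_indels(filt$retained, reference, params)
  calls <- rbind(snvs, indels)

  cnv <- NULL
  if (!is.null(panel) && length(panel) >= 2L) {
    depths <- dcs_depth_by_region(filt$retained, panel)
    cnv <- call_cnv(depths, params)
  }
  fp <- if (!is.null(identity_loci))
    snp_fingerprint(filt$retained, identity_loci, params) else NULL

  counts <- c(
    pre$counts,
    stranded_reads = nrow(placed$reads),
    unplaced = nrow(placed$unplaced),
    families = length(grouped$families),
    undersized_families = nrow(grouped$undersized),
    sscs = length(sscs$sscs),
    dcs = length(duplex$dcs),
    sscs_unpaired = length(duplex$unpaired),
    sscs_ambiguous = length(duplex$ambiguous),
    dcs_discarded_n = nrow(duplex$discarded),
    dcs_dropped_mismatches = nrow(filt$dropped),
    dcs_retained = length(filt$retained),
    snv_calls = nrow(snvs),
    indel_calls = nrow(indels)
  )

  outputs <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    outputs <- c(
      vcf = write_vcf(calls, reference, file.path(outdir, "calls.vcf")),
      drops = write_log_tsv(pre$drops, file.path(outdir, "drop_log.tsv")),
      sam = write_consensus_sam(duplex$dcs, reference,
                                file.path(outdir, "dcs.sam"))
    )
    if (!is.null(cnv))
      outputs["cnv"] <- write_log_tsv(cnv, file.path(outdir, "cnv.tsv"))
    report <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, counts = as.list(counts))
    outputs["report"] <- write_report_json(report,
                                           file.path(outdir, "report.json"))
  }

  structure(list(counts = counts, calls = calls, cnv = cnv, fingerprint = fp,
                 seed = seed, outputs = outputs),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("duplex pipeline run (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$counts)) cat(sprintf("  %-26s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  calls: %d\n", nrow(x$calls)))
  invisible(x)
}
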