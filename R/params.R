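#' Pipeline parameters and filter thresholds
#'
#' Collects every numeric threshold the pipeline applies, from read
#' pre-processing through duplex consensus assembly, variant calling and
#' ddPCR sample QC. The defaults are the operating point of the workflow:
#' reads are uniformed to 150 bases; mates with a homopolymer run longer
#' than 35 nt within the first 50 nt are removed; the 12-nt duplex tag is
#' located by an invariant 5-bp anchor and tags containing a homopolymer
#' longer than 9 bases are discarded; a tag family needs at least 2 members;
#' a consensus base requires at least 70% coherent members; duplex consensus
#' sequences (DCSs) with more than 30% 'N' are discarded; aligned DCSs with
#' more than 7 reference mismatches are dropped and bases below phred 30 are
#' masked; an SNV needs more than two supporting DCSs (i.e. >= 3 distinct
#' molecules) at >= 3x DCS depth; indels need >= 3 altered DCSs; a region is
#' called amplified when its depth log2 ratio exceeds 1; a ddPCR reaction
#' with fewer than 100 total events is unsuitable.
#'
#' @param read_length uniform read length in bases after padding.
#' @param pad_base base appended to short reads (quality 0).
#' @param tag_length length of the random duplex tag on each mate.
#' @param anchor_len length of the invariant ligation-site anchor.
#' @param pre_homopolymer_len maximum tolerated homopolymer run length in the
#'   leading window; runs strictly longer cause the pair to be dropped.
#' @param pre_homopolymer_window number of leading bases scanned for runs.
#' @param tag_homopolymer_max maximum tolerated homopolymer run inside the
#'   tag; strictly longer runs cause a drop.
#' @param min_family_members minimum reads per tag family for an SSCS.
#' @param consensus_fraction minimum fraction of coherent members for a
#'   consensus base (inclusive).
#' @param max_n_fraction maximum fraction of 'N' in an emitted DCS, and the
#'   per-position member-N fraction above which 'N' is forced (both strict).
#' @param max_dcs_mismatches maximum reference mismatches for a retained DCS
#'   (strictly more are dropped), counted before quality masking.
#' @param min_phred bases below this phred score are masked to 'N'.
#' @param min_supporting_dcs minimum distinct DCSs supporting an SNV.
#' @param min_dcs_depth minimum DCS depth at an emitted SNV position.
#' @param min_indel_dcs minimum altered DCSs supporting an indel.
#' @param head_tail_window bases at each DCS end treated as the head/tail
#'   artifact window for SNV evidence.
#' @param cnv_log2_threshold log2 depth-ratio above which (strictly) a region
#'   is called amplified.
#' @param min_ddpcr_events minimum total droplet events for a suitable ddPCR
#'   reaction.
#'
#' @return an object of class `pipeline_params` (a validated list).
#' @export
pipeline_params <- function(read_length = 150L,
                            pad_base = "N",
                            tag_length = 12L,
                            anchor_len = 5L,
                            pre_homopolymer_len = 35L,
                            pre_homopolymer_window = 50L,
                            tag_homopolymer_max = 9L,
                            min_family_members = 2L,
                            consensus_fraction = 0.70,
                            max_n_fraction = 0.30,
                            max_dcs_mismatches = 7L,
                            min_phred = 30L,
                            min_supporting_dcs = 3L,
                            min_dcs_depth = 3L,
                            min_indel_dcs = 3L,
                            head_tail_window = 5L,
                            cnv_log2_threshold = 1.0,
                            min_ddpcr_events = 100L) {
  p <- list(
    read_length = as.integer(read_length),
    pad_base = as.character(pad_base),
    tag_length = as.integer(tag_length),
    anchor_len = as.integer(anchor_len),
    pre_homopolymer_len = as.integer(pre_homopolymer_len),
    pre_homopolymer_window = as.integer(pre_homopolymer_window),
    tag_homopolymer_max = as.integer(tag_homopolymer_max),
    min_family_members = as.integer(min_family_members),
    consensus_fraction = as.numeric(consensus_fraction),
    max_n_fraction = as.numeric(max_n_fraction),
    max_dcs_mismatches = as.integer(max_dcs_mismatches),
    min_phred = as.integer(min_phred),
    min_supporting_dcs = as.integer(min_supporting_dcs),
    min_dcs_depth = as.integer(min_dcs_depth),
    min_indel_dcs = as.integer(min_indel_dcs),
    head_tail_window = as.integer(head_tail_window),
    cnv_log2_threshold = as.numeric(cnv_log2_threshold),
    min_ddpcr_events = as.integer(min_ddpcr_events)
  )
  counts <- c("read_length", "tag_length", "anchor_len", "pre_homopolymer_len",
              "pre_homopolymer_window", "tag_homopolymer_max",
              "min_family_members", "max_dcs_mismatches", "min_phred",
              "min_supporting_dcs", "min_dcs_depth", "min_indel_dcs",
              "head_tail_window", "min_ddpcr_events")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 0L)
      stop("pipeline_params: '", nm, "' must be a non-negative integer")
  }
  for (nm in c("consensus_fraction", "max_n_fraction")) {
    if (is.na(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop("pipeline_params: '", nm, "' must lie in (0, 1]")
  }
  if (nchar(p$pad_base) != 1L)
    stop("pipeline_params: 'pad_base' must be a single base")
  structure(p, class = "pipeline_params")
}

#' Load pipeline parameters from a YAML file
#'
#' Reads a YAML mapping whose keys are `pipeline_params()` argument names and
#' returns a validated parameter object; unknown keys are rejected so that
#' typos in a configuration file cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param base parameter object supplying defaults for keys not in the file.
#' @return a `pipeline_params` object.
#' @export
params_from_yaml <- function(path, base = pipeline_params()) {
  stopifnot(file.exists(path))
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  known <- names(unclass(base))
  bad <- setdiff(names(ov), known)
  if (length(bad))
    stop("params_from_yaml: unknown parameter key(s): ", paste(bad, collapse = ", "))
  merged <- utils::modifyList(unclass(base), ov)
  do.call(pipeline_params, merged)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("duplex pipeline parameters:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# inclusive "at least" comparison robust to binary representation of fractions
.at_least_frac <- function(count, total, frac) count >= frac * total - 1e-9

# strict "more than" comparison with the same guard
.more_than_frac <- function(count, total, frac) count > frac * total + 1e-9
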