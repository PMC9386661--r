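#' ddPCR fractional abundance
#'
#' Fractional abundance of the mutant allele in percent,
#' `F.A.% = 100 * Nmut / (Nmut + Nwt)`, where `Nmut` and `Nwt` are the mutant
#' and wild-type droplet event counts of one reaction. A reaction with zero
#' total events has no defined abundance; such samples fail the suitability
#' QC upstream of this computation.
#'
#' @param n_mut mutant droplet events.
#' @param n_wt wild-type droplet events.
#' @return fractional abundance in percent, in \[0, 100\].
#' @examples
#' fractional_abundance(28, 9972)  # 0.28
#' @export
fractional_abundance <- function(n_mut, n_wt) {
  if (any(is.na(n_mut)) || any(is.na(n_wt)) || any(n_mut < 0) || any(n_wt < 0))
    stop("fractional_abundance: event counts must be non-negative")
  tot <- n_mut + n_wt
  if (any(tot == 0))
    stop("fractional_abundance: zero total events; abundance undefined ",
         "(sample should have been flagged unsuitable by the <100-event QC)")
  100 * n_mut / tot
}

#' One ddPCR assay replicate
#'
#' Bundles one replicate's droplet counts with its derived fractional
#' abundance and suitability verdict (a reaction with fewer than
#' `min_events` total events is unsuitable).
#'
#' @param assay_id assay identifier (e.g. `"KRAS_G12_G13"`, `"BRAF_V600E"`).
#' @param replicate_id replicate label.
#' @param n_mut,n_wt droplet event counts.
#' @param min_events suitability threshold on total events.
#' @return one-row data frame with columns `assay_id`, `replicate_id`,
#'   `n_mut`, `n_wt`, `fa_percent` (NA when total is 0), `suitable`.
#' @export
ddpcr_assay_result <- function(assay_id, replicate_id, n_mut, n_wt,
                               min_events = 100L) {
  if (n_mut < 0 || n_wt < 0) stop("ddpcr_assay_result: negative counts")
  tot <- n_mut + n_wt
  data.frame(
    assay_id = assay_id, replicate_id = as.character(replicate_id),
    n_mut = as.integer(n_mut), n_wt = as.integer(n_wt),
    fa_percent = if (tot > 0) fractional_abundance(n_mut, n_wt) else NA_real_,
    suitable = tot >= min_events,
    stringsAsFactors = FALSE
  )
}

#' Reconcile technical replicates of one ddPCR assay
#'
#' Each sample is run in at least two technical replicates; a mutation is
#' considered validated when at least two suitable replicates each show
#' mutant events (`rule = "validated"`). A permissive mode calls mutant on
#' any positive suitable replicate. The assay is unsuitable only when every
#' replicate fails the 100-event QC. When fewer than `min_replicates`
#' suitable replicates are available, the verdict is flagged low-confidence.
#'
#' @param results data frame of replicates for one assay, as rows produced by
#'   [ddpcr_assay_result()].
#' @param min_replicates suitable replicates needed for full confidence.
#' @param rule `"validated"` (>= 2 positive suitable replicates) or
#'   `"permissive"` (>= 1).
#' @return list with `assay_id`, `status` in `wt | mutant | unsuitable`,
#'   `low_confidence` flag, `fa_percent` (mean over positive suitable
#'   replicates; NA unless mutant), and replicate tallies.
#' @export
reconcile_replicates <- function(results, min_replicates = 2L,
                                 rule = c("validated", "permissive")) {
  rule <- match.arg(rule)
  if (nrow(results) < 1L) stop("reconcile_replicates: need at least one replicate")
  if (length(unique(results$assay_id)) != 1L)
    stop("reconcile_replicates: mixed assay_ids: ",
         paste(unique(results$assay_id), collapse = ", "))
  suit <- results[results$suitable, , drop = FALSE]
  n_pos <- sum(suit$n_mut > 0L)
  need <- if (rule == "validated") 2L else 1L
  status <-
    if (nrow(suit) == 0L) "unsuitable"
    else if (n_pos >= need) "mutant"
    else "wt"
  list(
    assay_id = results$assay_id[1L],
    status = status,
    low_confidence = status != "unsuitable" && nrow(suit) < min_replicates,
    fa_percent = if (status == "mutant")
      mean(suit$fa_percent[suit$n_mut > 0L]) else NA_real_,
    n_replicates = nrow(results),
    n_suitable = nrow(suit),
    n_positive_suitable = n_pos
  )
}

#' Default ctDNA triage assay panel
#'
#' The monitored resistance-mutation assays covering RAS hotspots, BRAF
#' V600E and the EGFR extracellular domain, with their gene assignments.
#'
#' @return data frame with columns `assay_id`, `gene`.
#' @export
triage_panel <- function() {
  data.frame(
    assay_id = c("KRAS_G12_G13", "KRAS_Q61", "NRAS_G12", "NRAS_G13D",
                 "NRAS_Q61", "BRAF_V600E", "EGFR_ECD"),
    gene = c("KRAS", "KRAS", "NRAS", "NRAS", "NRAS", "BRAF", "EGFR"),
    stringsAsFactors = FALSE
  )
}

#' Zero-mutation ctDNA triage decision for one patient
#'
#' Applies the eligibility rule over the reconciled per-assay statuses:
#' the patient is molecularly eligible only when every monitored assay is
#' suitable and no mutation is detected; any detected mutation makes the
#' patient ineligible; with no detection but at least one unsuitable assay
#' the sample is unsuitable.
#'
#' @param patient_id patient identifier.
#' @param assay_status named character vector or data frame
#'   (`assay_id`, `status`, optionally `fa_percent`) of reconciled statuses in
#'   `wt | mutant | unsuitable`, covering the whole panel.
#' @param panel panel definition as from [triage_panel()].
#' @return list of class `triage_decision` with `patient_id`, `status` in
#'   `eligible | ineligible | unsuitable_sample`, `assay_status`, and
#'   `detected_mutations` (data frame `gene`, `assay_id`, `fa_percent`).
#' @export
triage_patient <- function(patient_id, assay_status, panel = triage_panel()) {
  if (is.character(assay_status)) {
    assay_status <- data.frame(assay_id = names(assay_status),
                               status = unname(assay_status),
                               fa_percent = NA_real_,
                               stringsAsFactors = FALSE)
  }
  if (is.null(assay_status$fa_percent)) assay_status$fa_percent <- NA_real_
  bad <- setdiff(assay_status$status, c("wt", "mutant", "unsuitable"))
  if (length(bad)) stop("triage_patient: unknown status value(s): ",
                        paste(bad, collapse = ", "))
  missing <- setdiff(panel$assay_id, assay_status$assay_id)
  if (length(missing))
    stop("triage_patient: panel assay(s) missing for ", patient_id, ": ",
         paste(missing, collapse = ", "))
  assay_status <- assay_status[match(panel$assay_id, assay_status$assay_id), ,
                               drop = FALSE]
  mut <- assay_status$status == "mutant"
  status <-
    if (any(mut)) "ineligible"
    else if (any(assay_status$status == "unsuitable")) "unsuitable_sample"
    else "eligible"
  detected <- data.frame(
    gene = panel$gene[mut],
    assay_id = assay_status$assay_id[mut],
    fa_percent = assay_status$fa_percent[mut],
    stringsAsFactors = FALSE
  )
  structure(list(patient_id = patient_id, status = status,
                 assay_status = assay_status, detected_mutations = detected),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("patient %s: %s", x$patient_id, x$status))
  if (nrow(x$detected_mutations))
    cat(" [", paste(x$detected_mutations$assay_id, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Triage a cohort from a ddPCR count table
#'
#' Runs suitability QC, replicate reconciliation and the zero-mutation triage
#' for every patient in a long-format droplet count table.
#'
#' @param counts data frame with columns `patient_id`, `assay_id`,
#'   `replicate_id`, `n_mut`, `n_wt`.
#' @param params pipeline parameters (supplies `min_ddpcr_events`).
#' @param rule replicate combination rule, see [reconcile_replicates()].
#' @param panel assay panel, see [triage_panel()].
#' @return list of `triage_decision` objects, one per patient.
#' @export
triage_cohort <- function(counts, params = pipeline_params(),
                          rule = "validated", panel = triage_panel()) {
  need <- c("patient_id", "assay_id", "replicate_id", "n_mut", "n_wt")
  if (!all(need %in% names(counts)))
    stop("triage_cohort: counts must have columns ", paste(need, collapse = ", "))
  lapply(split(counts, counts$patient_id), function(pc) {
    recs <- lapply(split(pc, pc$assay_id), function(ac) {
      reps <- do.call(rbind, lapply(seq_len(nrow(ac)), function(i)
        ddpcr_assay_result(ac$assay_id[i], ac$replicate_id[i],
                           ac$n_mut[i], ac$n_wt[i],
                           min_events = params$min_ddpcr_events)))
      reconcile_replicates(reps, rule = rule)
    })
    st <- data.frame(
      assay_id = vapply(recs, `[[`, "", "assay_id"),
      status = vapply(recs, `[[`, "", "status"),
      fa_percent = vapply(recs, `[[`, 0, "fa_percent"),
      stringsAsFactors = FALSE
    )
    triage_patient(pc$patient_id[1L], st, panel = panel)
  })
}

#' Screening cohort summary
#'
#' Cohort-level counts and percentages over triage decisions: patients
#' carrying at least one resistance mutation, per-gene patient counts (a
#' patient counts once per gene however many alleles were found), and the
#' molecularly eligible count. Percentages use the screened denominator and
#' round half-up to integers.
#'
#' @param decisions list of `triage_decision` objects.
#' @return list with `n_screened`, `n_mutant`, `pct_mutant`, `n_eligible`,
#'   `n_unsuitable`, and a data frame `by_gene` (`gene`, `n`, `pct`).
#' @export
screening_summary <- function(decisions) {
  n <- length(decisions)
  genes <- c("KRAS", "NRAS", "BRAF", "EGFR")
  if (n == 0L) {
    return(list(n_screened = 0L, n_mutant = 0L, pct_mutant = 0,
                n_eligible = 0L, n_unsuitable = 0L,
                by_gene = data.frame(gene = genes, n = 0L, pct = 0)))
  }
  status <- vapply(decisions, `[[`, "", "status")
  gene_hits <- lapply(decisions, function(d) unique(d$detected_mutations$gene))
  by_gene <- data.frame(
    gene = genes,
    n = vapply(genes, function(g)
      sum(vapply(gene_hits, function(h) g %in% h, TRUE)), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  by_gene$pct <- .round_half_up(100 * by_gene$n / n)
  list(
    n_screened = n,
    n_mutant = sum(status == "ineligible"),
    pct_mutant = .round_half_up(100 * mean(status == "ineligible")),
    n_eligible = sum(status == "eligible"),
    n_unsuitable = sum(status == "unsuitable_sample"),
    by_gene = by_gene
  )
}

#' Synthetic screening cohort at the reported marginals
#'
#' Constructs a synthetic 52-patient ddPCR screening count table matching
#' the trial's published screening margins: 13 patients KRAS-positive (8 of
#' them at codon 61, the most frequent RAS alleles), 4 NRAS-positive, 1
#' BRAF-positive and 3 EGFR-ECD-positive, with 16 patients carrying at
#' least one mutation and 5 of those carrying mutations in two genes. The
#' per-droplet counts are invented (only patient-level margins are publicly
#' reported); the object is a synthetic stand-in for the real screening
#' data, which is not available at patient level.
#'
#' @param n_wt_background wild-type droplet events per reaction.
#' @return data frame in the [triage_cohort()] layout (`patient_id`,
#'   `assay_id`, `replicate_id`, `n_mut`, `n_wt`).
#' @export
synthetic_screening_cohort <- function(n_wt_background = 5000L) {
  panel <- triage_panel()
  pts <- sprintf("S%02d", 1:52)
  pos <- list()
  for (i in 1:8) pos[[pts[i]]] <- "KRAS_Q61"
  for (i in 9:13) pos[[pts[i]]] <- "KRAS_G12_G13"
  for (i in 1:4) pos[[pts[i]]] <- c(pos[[pts[i]]], "NRAS_Q61")
  pos[[pts[5]]] <- c(pos[[pts[5]]], "BRAF_V600E")
  for (i in 14:16) pos[[pts[i]]] <- "EGFR_ECD"
  rows <- list()
  for (p in pts) {
    for (a in panel$assay_id) {
      mut <- a %in% pos[[p]]
      for (r in 1:2) {
        nm <- if (mut) c(40L, 35L)[r] else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p, assay_id = a, replicate_id = r,
          n_mut = nm, n_wt = n_wt_background - nm,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Read a ddPCR droplet count table
#'
#' @param path TSV with columns `patient_id`, `assay_id`, `replicate_id`,
#'   `n_mut`, `n_wt`.
#' @return data frame in the layout [triage_cohort()] expects.
#' @export
read_ddpcr_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "assay_id", "replicate_id", "n_mut", "n_wt")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("read_ddpcr_tsv: missing column(s): ", paste(miss, collapse = ", "))
  x
}
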