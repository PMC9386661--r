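#!/usr/bin/env Rscript
# Quantify duplex error suppression: simulate a 2,000-molecule library with
# 1% strand-independent per-base sequencing error, run the consensus stages,
# and compare the raw-read error rate against the DCS error rate. A second
# run with strand-coincident errors shows which artifacts the duplex
# principle cannot remove.

suppressPackageStartupMessages({
  library(duplexct)
  library(Biostrings)
})
dir.create("results", showWarnings = FALSE)

reference <- local({
  set.seed(2)
  c(panel_amplicon = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                           collapse = ""))
})

# per-base mismatch rate of the sequenced reads against the ideal reads
# reconstructed from the reference and the truth placements
raw_rate <- function(lib, cfg) {
  mols <- lib$truth$molecules
  core_len <- cfg$read_length - cfg$tag_length - nchar(cfg$anchor)
  frag <- substring(reference[mols$contig], mols$start + 1,
                    mols$start + mols$frag_len_ref)
  rcfrag <- as.character(reverseComplement(DNAStringSet(frag)))
  fwd <- substr(frag, 1, core_len)
  rev <- substr(rcfrag, 1, core_len)
  mm <- 0; tot <- 0
  for (k in c("r1", "r2")) {
    rd <- lib[[k]]
    mol <- as.integer(sub("^M0*([0-9]+):.*", "\\1", rd$id))
    strand <- as.integer(sub("^M[0-9]+:S([12]):.*", "\\1", rd$id))
    want <- if (k == "r1") ifelse(strand == 1, fwd[mol], rev[mol])
            else ifelse(strand == 1, rev[mol], fwd[mol])
    have <- substr(rd$seq, cfg$tag_length + nchar(cfg$anchor) + 1,
                   cfg$read_length)
    for (i in seq_along(have)) {
      a <- strsplit(have[i], "")[[1]]; b <- strsplit(want[i], "")[[1]]
      use <- seq_len(min(length(a), length(b)))
      mm <- mm + sum(a[use] != b[use]); tot <- tot + length(use)
    }
  }
  # tag and anchor bases also sequenced but have no reference ideal; the
  # core rate estimates the same per-base process
  mm / tot
}

run_case <- function(label, per_base, coincident) {
  cfg <- sim_config(reference, n_molecules = 2000,
                    per_base_error_rate = per_base,
                    coincident_error_rate = coincident, seed = 42)
  lib <- simulate_duplex_library(cfg)
  pre <- preprocess_pairs(lib$r1, lib$r2, anchor = cfg$anchor)
  placed <- placements_from_truth(pre$kept, lib$truth)
  duplex <- pair_and_build_dcs(build_all_sscs(group_families(placed$reads))$sscs)
  retained <- filter_dcs(align_dcs(duplex$dcs, reference), reference)$retained

  dmm <- 0; dtot <- 0
  for (d in retained) {
    refseg <- substr(reference[[d$contig]], d$start + 1, d$end)
    c1 <- strsplit(d$bases, "")[[1]]; c2 <- strsplit(refseg, "")[[1]]
    use <- c1 != "N"
    dmm <- dmm + sum(c1[use] != c2[use]); dtot <- dtot + sum(use)
  }
  raw <- raw_rate(lib, cfg)
  data.frame(case = label, raw_rate = raw, dcs_rate = dmm / dtot,
             dcs_bases = dtot,
             suppression = raw / max(dmm / dtot, .Machine$double.eps))
}

tab <- rbind(
  run_case("strand_independent_1e-2", 1e-2, 0),
  run_case("strand_coincident_1e-2", 0, 1e-2)
)
write_log_tsv(tab, "results/error_suppression.tsv")
print(tab, row.names = FALSE)
message("Strand-independent errors are removed by duplex agreement; ",
        "strand-coincident artifacts survive, as expected.")
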