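#!/usr/bin/env Rscript
# Simulate a duplex-tagged ctDNA-like read library with a known 1% spike-in
# and write the FASTQ pair, the ground-truth tables and the configuration
# under results/sim/. Downstream scripts regenerate their own libraries in
# memory; this script exists to produce inspectable files.

suppressPackageStartupMessages(library(duplexct))

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
set.seed(1)

reference <- c(panel_amplicon = paste(
  sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""))
pos <- 200L
refb <- substr(reference, pos, pos)
altb <- setdiff(c("A", "C", "G", "T"), refb)[1]

cfg <- sim_config(
  reference = reference,
  n_molecules = 500,
  per_base_error_rate = 3e-3,
  spiked_variants = data.frame(contig = "panel_amplicon", pos = pos,
                               ref = refb, alt = altb, af = 0.01),
  seed = 20260101
)

lib <- simulate_duplex_library(cfg)
write_fastq_pairs(lib, "results/sim/library")
write_truth(lib$truth, "results/sim/truth")
write_sim_config(cfg, "results/sim/config.yaml")

v <- lib$truth$variants
message(sprintf(
  "simulated %d molecules -> %d read pairs; spike-in %s>%s at %.2f%% (realized %.2f%%, %d/%d molecules)",
  nrow(lib$truth$molecules), nrow(lib$r1), refb, altb, 100 * v$af,
  100 * v$realized_fraction, v$n_carriers, v$n_overlapping))
message("wrote results/sim/{library_R1.fastq,library_R2.fastq,truth.*,config.yaml}")
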