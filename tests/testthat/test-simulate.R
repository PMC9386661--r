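# Synthetic duplex library generator

test_that("with no errors and no variants every read matches the reference", {
  ref <- rand_ref(400, seed = 21)
  pos <- 150L
  sv <- data.frame(contig = "chr1", pos = pos,
                   ref = substr(ref, pos, pos),
                   alt = setdiff(c("A", "C", "G", "T"),
                                 substr(ref, pos, pos))[1],
                   af = 0)
  cfg <- sim_config(ref, n_molecules = 60, per_base_error_rate = 0,
                    spiked_variants = sv, seed = 5)
  lib <- simulate_duplex_library(cfg)
  expect_equal(nrow(lib$truth$edits), 0L)

  mols <- lib$truth$molecules
  core_len <- cfg$read_length - cfg$tag_length - nchar(cfg$anchor)
  for (k in c("r1", "r2")) {
    rd <- lib[[k]]
    for (i in seq_len(nrow(rd))) {
      m <- as.integer(sub("^M0*([0-9]+):.*", "\\1", rd$id[i]))
      frag <- substr(ref, mols$start[m] + 1, mols$start[m] + mols$frag_len_ref[m])
      core <- substr(rd$seq[i], cfg$tag_length + nchar(cfg$anchor) + 1,
                     cfg$read_length)
      core <- sub("N+$", "", core)
      fwd <- substr(frag, 1, core_len)
      rev <- substr(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag))), 1, core_len)
      expect_true(core == fwd || core == rev, label = rd$id[i])
    }
  }
})

test_that("identical configurations give byte-identical libraries", {
  ref <- rand_ref(300, seed = 8)
  mk <- function() sim_config(ref, n_molecules = 50,
                              per_base_error_rate = 5e-3,
                              low_qual_rate = 0.02, seed = 99)
  a <- simulate_duplex_library(mk())
  b <- simulate_duplex_library(mk())
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_identical(a$truth$molecules, b$truth$molecules)
  # and byte-identical FASTQ files
  d <- withr::local_tempdir()
  write_fastq_pairs(a, file.path(d, "a"))
  write_fastq_pairs(b, file.path(d, "b"))
  expect_identical(readBin(file.path(d, "a_R1.fastq"), "raw", 1e6),
                   readBin(file.path(d, "b_R1.fastq"), "raw", 1e6))
})

test_that("read-pair count equals the sum of per-strand family sizes", {
  ref <- rand_ref(300, seed = 3)
  cfg <- sim_config(ref, n_molecules = 120, seed = 4)
  lib <- simulate_duplex_library(cfg)
  m <- lib$truth$molecules
  expect_equal(nrow(lib$r1), sum(m$n_reads_s1 + m$n_reads_s2))
  expect_equal(nrow(lib$r2), nrow(lib$r1))
  expect_identical(lib$r1$id, lib$r2$id)
})

test_that("zero molecules give an empty library, not an error", {
  ref <- rand_ref(300, seed = 3)
  lib <- simulate_duplex_library(sim_config(ref, n_molecules = 0, seed = 1))
  expect_equal(nrow(lib$r1), 0L)
  expect_equal(nrow(lib$truth$molecules), 0L)
})

test_that("realized mutant-molecule fraction is binomial around the allele fraction", {
  ref <- rand_ref(400, seed = 13)
  pos <- 200L
  sv <- data.frame(contig = "chr1", pos = pos, ref = substr(ref, pos, pos),
                   alt = setdiff(c("A", "C", "G", "T"),
                                 substr(ref, pos, pos))[1],
                   af = 0.5)
  cfg <- sim_config(ref, n_molecules = 2000, per_base_error_rate = 0,
                    spiked_variants = sv, seed = 77)
  lib <- simulate_duplex_library(cfg)
  v <- lib$truth$variants
  ival <- stats::qbinom(c(0.005, 0.995), v$n_overlapping, 0.5) / v$n_overlapping
  expect_gte(v$realized_fraction, ival[1])
  expect_lte(v$realized_fraction, ival[2])
  # the recorded per-molecule edits recompute the aggregate fraction
  expect_equal(v$n_carriers, length(unique(lib$truth$edits$mol)))
})

test_that("empirical per-base mismatch rate matches the configured error rate", {
  ref <- rand_ref(300, seed = 31)
  cfg <- sim_config(ref, n_molecules = 400, per_base_error_rate = 8e-3,
                    seed = 19)
  er <- library_error_rate(cfg)
  se <- sqrt(8e-3 * (1 - 8e-3) / er$bases)
  expect_lt(abs(er$rate - 8e-3), 3 * se)
})

test_that("invalid variant specifications are rejected with explicit messages", {
  ref <- rand_ref(200, seed = 2)
  expect_error(sim_config(ref, 10, spiked_variants = data.frame(
    contig = "chr1", pos = 500L, ref = "A", alt = "T", af = 0.1)),
    "outside the reference")
  expect_error(sim_config(ref, 10, spiked_variants = data.frame(
    contig = "chrX", pos = 50L, ref = "A", alt = "T", af = 0.1)),
    "not in reference")
  wrong <- setdiff(c("A", "C", "G", "T"), substr(ref, 50, 50))[1]
  expect_error(sim_config(ref, 10, spiked_variants = data.frame(
    contig = "chr1", pos = 50L, ref = wrong, alt = "T", af = 0.1)),
    "does not match reference")
  expect_error(sim_config(ref, 10, spiked_variants = data.frame(
    contig = "chr1", pos = 50L, ref = substr(ref, 50, 50), alt = "T",
    af = 1.5)), "allele_fraction")
  expect_error(sim_config(ref, 10, per_base_error_rate = 0.7), "error_rate")
})

test_that("configuration and truth tables round-trip through YAML/TSV", {
  ref <- rand_ref(250, seed = 41)
  sv <- data.frame(contig = "chr1", pos = 100L, ref = substr(ref, 100, 100),
                   alt = setdiff(c("A", "C", "G", "T"),
                                 substr(ref, 100, 100))[1],
                   af = 0.25)
  cfg <- sim_config(ref, n_molecules = 30, spiked_variants = sv, seed = 6)
  d <- withr::local_tempdir()
  write_sim_config(cfg, file.path(d, "cfg.yaml"))
  cfg2 <- read_sim_config(file.path(d, "cfg.yaml"))
  expect_equal(cfg2$reference, cfg$reference)
  expect_equal(cfg2$seed, cfg$seed)
  expect_identical(simulate_duplex_library(cfg2)$r1,
                   simulate_duplex_library(cfg)$r1)

  lib <- simulate_duplex_library(cfg)
  write_truth(lib$truth, file.path(d, "truth"))
  back <- read_truth(file.path(d, "truth"))
  expect_equal(back$molecules, lib$truth$molecules)
  expect_equal(back$variants$realized_fraction,
               lib$truth$variants$realized_fraction)
})
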