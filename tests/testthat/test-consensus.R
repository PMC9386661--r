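# Family grouping, SSCS and DCS assembly

mk_reads <- function(tags, starts, seqs, contig = "chr1", strand = "+") {
  n <- length(tags)
  data.frame(id = sprintf("r%d", seq_len(n)), merged_tag = tags,
             contig = contig, start = starts,
             end = starts + nchar(seqs), strand = strand,
             cigar = paste0(nchar(seqs), "M"),
             seq = seqs, qual = strrep("F", nchar(seqs)),
             stringsAsFactors = FALSE)
}

test_that("families are keyed on tag plus genomic coordinates", {
  tag <- paste0(strrep("AC", 6), strrep("GT", 6))
  s <- rand_seq(50)
  g <- group_families(mk_reads(rep(tag, 3), rep(10L, 3), rep(s, 3)))
  expect_length(g$families, 1L)
  expect_equal(g$families[[1]]$n, 3L)

  # same tag, starts differing by one base: two singletons, both excluded
  g <- group_families(mk_reads(rep(tag, 2), c(10L, 11L), rep(s, 2)))
  expect_length(g$families, 0L)
  expect_equal(nrow(g$undersized), 2L)

  expect_error(group_families(mk_reads(tag, NA_integer_, s)),
               "without placement")
})

test_that("random partitions equal the sort-and-scan grouping oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    tags <- sample(replicate(4, paste0(rand_seq(12), rand_seq(12))), n, TRUE)
    starts <- sample(c(0L, 5L, 9L), n, TRUE)
    reads <- mk_reads(tags, starts, vapply(seq_len(n), function(i)
      rand_seq(20), ""))
    g <- group_families(reads, pipeline_params(min_family_members = 1L))
    got <- sort(vapply(g$families, `[[`, 0L, "n"))
    expect_equal(got, oracle_group(reads))
  }
})

test_that("SSCS consensus applies the 70% and 30%-N rules with exact boundaries", {
  p <- pipeline_params()
  fam <- function(seqs) list(key = "k", merged_tag = strrep("A", 24),
                             contig = "chr1", start = 0L,
                             end = nchar(seqs[1]), strand = "+",
                             cigar = paste0(nchar(seqs[1]), "M"),
                             seqs = seqs, quals = rep(strrep("F", nchar(seqs[1])), length(seqs)),
                             n = length(seqs))

  # full agreement reproduces the read
  s <- rand_seq(40)
  expect_identical(build_sscs(fam(rep(s, 3)), p)$bases, s)

  # 2-of-3 (66.7%) is below the 70% floor -> N
  a <- paste0("A", substr(s, 2, 40))
  b <- paste0("C", substr(s, 2, 40))
  cons <- build_sscs(fam(c(a, a, b)), p)
  expect_identical(substr(cons$bases, 1, 1), "N")
  expect_identical(substr(cons$bases, 2, 40), substr(s, 2, 40))

  # 7-of-10 is exactly 70% -> kept (inclusive boundary)
  c7 <- paste0("C", substr(s, 2, 40))
  t3 <- paste0("T", substr(s, 2, 40))
  cons <- build_sscs(fam(c(rep(c7, 7), rep(t3, 3))), p)
  expect_identical(substr(cons$bases, 1, 1), "C")

  # >30% of members N at a position forces N even with full coherence
  nn <- paste0("N", substr(s, 2, 40))
  cons <- build_sscs(fam(c(rep(s, 6), rep(nn, 4))), p)   # 40% N
  expect_identical(substr(cons$bases, 1, 1), "N")
  cons <- build_sscs(fam(c(rep(s, 7), rep(nn, 3))), p)   # exactly 30%: kept
  expect_identical(substr(cons$bases, 1, 1), substr(s, 1, 1))

  # undersized families build no consensus
  expect_null(build_sscs(fam(s), p))
  # unequal member lengths are an upstream bug
  expect_error(build_sscs(fam(c(s, substr(s, 1, 30))), p), "unequal")
})

test_that("SSCS is invariant under member permutation and matches the oracle", {
  set.seed(61)
  p <- pipeline_params()
  fam <- function(seqs) list(key = "k", merged_tag = strrep("A", 24),
                             contig = "chr1", start = 0L,
                             end = nchar(seqs[1]), strand = "+",
                             cigar = paste0(nchar(seqs[1]), "M"),
                             seqs = seqs, quals = rep(strrep("F", nchar(seqs[1])), length(seqs)),
                             n = length(seqs))
  for (i in 1:200) {
    n <- sample(2:8, 1)
    L <- sample(5:30, 1)
    seqs <- replicate(n, rand_seq(L, c("A", "C", "G", "T", "N")))
    got <- build_sscs(fam(seqs), p)$bases
    expect_identical(got, oracle_sscs(seqs))
    perm <- sample(seqs)
    expect_identical(build_sscs(fam(perm), p)$bases, got)
  }
})

test_that("duplex pairing matches transposed tags and masks disagreements", {
  p <- pipeline_params()
  s <- rand_seq(100)
  ab <- paste0(strrep("AC", 6), strrep("GT", 6))
  ba <- duplexct:::.transpose_tag(ab)
  gd <- paste0(strrep("AG", 6), strrep("CT", 6))

  # identical strands: DCS equals them, no N
  d <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s),
                               make_sscs(ba, "chr1", 0L, s)), p)
  expect_length(d$dcs, 1L)
  expect_identical(d$dcs[[1]]$bases, s)
  expect_equal(d$dcs[[1]]$n_fraction, 0)

  # transpose-matching oracle on {ab, ba, gd}: one DCS, gd unpaired
  d <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s),
                               make_sscs(ba, "chr1", 0L, s),
                               make_sscs(gd, "chr1", 0L, s)), p)
  expect_length(d$dcs, 1L)
  expect_length(d$unpaired, 1L)

  # 31 disagreements in 100 bases -> >30% N -> discarded
  s2 <- s
  flip <- function(x) chartr("ACGT", "TGCA", x)
  substr(s2, 1, 31) <- flip(substr(s, 1, 31))
  d <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s),
                               make_sscs(ba, "chr1", 0L, s2)), p)
  expect_length(d$dcs, 0L)
  expect_equal(nrow(d$discarded), 1L)
  expect_equal(d$discarded$n_fraction, 0.31)

  # exactly 30% N is retained (strictly more than 30% is discarded)
  s3 <- s
  substr(s3, 1, 30) <- flip(substr(s, 1, 30))
  d <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s),
                               make_sscs(ba, "chr1", 0L, s3)), p)
  expect_length(d$dcs, 1L)
  expect_equal(d$dcs[[1]]$n_fraction, 0.30)

  # symmetry: input order never changes the consensus string
  s4 <- s
  substr(s4, 5, 9) <- flip(substr(s, 5, 9))
  d1 <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s),
                                make_sscs(ba, "chr1", 0L, s4)), p)
  d2 <- pair_and_build_dcs(list(make_sscs(ba, "chr1", 0L, s4),
                                make_sscs(ab, "chr1", 0L, s)), p)
  expect_identical(d1$dcs[[1]]$bases, d2$dcs[[1]]$bases)
  expect_identical(d1$dcs[[1]]$bases, oracle_dcs(s, s4))

  # N in either strand propagates to the DCS
  s5 <- s
  substr(s5, 3, 3) <- "N"
  d <- pair_and_build_dcs(list(make_sscs(ab, "chr1", 0L, s5),
                               make_sscs(ba, "chr1", 0L, s)), p)
  expect_identical(substr(d$dcs[[1]]$bases, 3, 3), "N")
})

test_that("strict mode additionally discards SSCSs over the N budget", {
  p <- pipeline_params()
  # 2-member family disagreeing at 40 of 100 positions: 40% N in the SSCS
  s <- rand_seq(100)
  s2 <- s
  substr(s2, 1, 40) <- chartr("ACGT", "TGCA", substr(s, 1, 40))
  fam <- list(key = "k", merged_tag = strrep("AG", 12), contig = "chr1",
              start = 0L, end = 100L, strand = "+", cigar = "100M",
              seqs = c(s, s2), quals = rep(strrep("F", 100), 2), n = 2L)
  grouped <- list(families = list(fam),
                  undersized = data.frame(key = character(0),
                                          n_members = integer(0)))
  default <- build_all_sscs(grouped, p)
  expect_length(default$sscs, 1L)
  strict <- build_all_sscs(grouped, p, strict_n = TRUE)
  expect_length(strict$sscs, 0L)
  expect_equal(strict$discarded_n$n_fraction, 0.40)
})

test_that("every SSCS is paired, unpaired, ambiguous or discarded exactly once", {
  ref <- rand_ref(400, seed = 71)
  cfg <- sim_config(ref, n_molecules = 200, per_base_error_rate = 5e-3,
                    seed = 12)
  st <- consensus_stage(cfg)
  d <- st$duplex
  expect_equal(2L * length(d$dcs) + length(d$unpaired) + length(d$ambiguous) +
                 2L * nrow(d$discarded), length(st$sscs$sscs))
})

test_that("duplex assembly suppresses strand-independent errors but not coincident ones", {
  ref <- rand_ref(400, seed = 81)
  # strand-independent sequencing errors vanish in the DCS
  cfg <- sim_config(ref, n_molecules = 300, per_base_error_rate = 1e-2,
                    seed = 31)
  st <- consensus_stage(cfg)
  indep <- dcs_error_rate(st$retained, ref)
  expect_gt(indep$bases, 10000)
  expect_lt(indep$rate, 1e-4)

  # strand-coincident errors survive to the DCS (positive control for the
  # duplex principle)
  cfg2 <- sim_config(ref, n_molecules = 300, per_base_error_rate = 0,
                     coincident_error_rate = 1e-2, seed = 32)
  st2 <- consensus_stage(cfg2)
  coin <- dcs_error_rate(st2$retained, ref)
  expect_gt(coin$rate, 5e-3)
})
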