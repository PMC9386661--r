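# DCS filters, SNV/indel calling, CNV ratios and the SNP fingerprint

with_subs <- function(s, at, flip = TRUE) {
  for (p in at) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- if (flip) chartr("ACGT", "TGCA", cur) else cur
  }
  s
}

test_that("the mismatch filter is strict at seven and counts pre-mask", {
  ref <- rand_ref(300, seed = 91)
  p <- pipeline_params()
  seg <- substr(ref, 51, 150)

  clean <- align_dcs(list(make_dcs("chr1", 50L, seg)), ref)
  expect_equal(clean[[1]]$mismatches, 0L)
  expect_length(filter_dcs(clean, ref, p)$retained, 1L)

  seven <- align_dcs(list(make_dcs("chr1", 50L, with_subs(seg, 1:7 * 10))), ref)
  expect_equal(seven[[1]]$mismatches, 7L)
  expect_length(filter_dcs(seven, ref, p)$retained, 1L)

  eight <- align_dcs(list(make_dcs("chr1", 50L, with_subs(seg, 1:8 * 10))), ref)
  f <- filter_dcs(eight, ref, p)
  expect_length(f$retained, 0L)
  expect_equal(f$dropped$reason, "too_many_mismatches")

  # low-quality bases cannot hide mismatches from the filter, but are
  # masked to N in retained DCSs
  q <- rep(37L, 100); q[10] <- 20L
  one <- align_dcs(list(make_dcs("chr1", 50L, with_subs(seg, 10), quals = q)),
                   ref)
  expect_equal(one[[1]]$mismatches, 1L)
  kept <- filter_dcs(one, ref, p)$retained[[1]]
  expect_identical(substr(kept$bases, 10, 10), "N")

  expect_error(align_dcs(list(make_dcs("chr1", 250L, seg)), ref),
               "past the end")
})

test_that("SNV support, depth and head/tail rules gate emission", {
  ref <- rand_ref(300, seed = 92)
  p <- pipeline_params()
  seg <- function(start) substr(ref, start + 1, start + 100)
  alt_at <- function(start, pos) with_subs(seg(start), pos - start)

  # 2 supporting of 10 covering: below "more than two DCSs"
  dcss <- c(lapply(1:2, function(i) make_dcs("chr1", 50L, alt_at(50L, 100L))),
            lapply(1:8, function(i) make_dcs("chr1", 50L, seg(50L))))
  al <- align_dcs(dcss, ref)
  expect_equal(nrow(call_snvs(al, ref, p)), 0L)
  v <- call_snvs(al, ref, p, verbose = TRUE)
  expect_equal(v$filter, "low_support")
  expect_equal(v$supporting_dcs, 2L)

  # 3 of 3 mid-molecule: emitted at VAF 1
  dcss <- lapply(1:3, function(i) make_dcs("chr1", 50L, alt_at(50L, 100L)))
  calls <- call_snvs(align_dcs(dcss, ref), ref, p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 100L)
  expect_equal(calls$vaf, 1)
  expect_equal(calls$dcs_depth, 3L)

  # evidence confined to the terminal window of every supporting DCS
  # (variant at reference position 53 = read offset 3 < window 5)
  dcss <- lapply(1:5, function(i) make_dcs("chr1", 50L, alt_at(50L, 53L)))
  expect_equal(nrow(call_snvs(align_dcs(dcss, ref), ref, p)), 0L)
  v <- call_snvs(align_dcs(dcss, ref), ref, p, verbose = TRUE)
  expect_equal(v$filter, "head_tail")
  # one staggered DCS placing the same variant mid-molecule rescues it
  dcss[[6]] <- make_dcs("chr1", 20L, with_subs(substr(ref, 21, 120), 33))
  calls <- call_snvs(align_dcs(dcss, ref), ref, p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$supporting_dcs, 6L)
})

test_that("random pileups equal the brute-force oracle", {
  set.seed(71)
  p <- pipeline_params()
  ref <- rand_ref(200, seed = 93)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    dcss <- lapply(seq_len(n), function(i) {
      start <- sample(0:100, 1)
      s <- substr(ref, start + 1, start + 100)
      nmut <- sample(0:3, 1)
      if (nmut) s <- with_subs(s, sample(100, nmut))
      make_dcs("chr1", start, s)
    })
    al <- align_dcs(dcss, ref)
    got <- call_snvs(al, ref, p)
    want <- oracle_snv_pileup(lapply(al, function(d)
      list(bases = d$bases, start = d$start)), ref)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$pos, want$pos)
      expect_equal(got$alt, want$alt)
      expect_equal(got$supporting_dcs, want$supporting_dcs)
      expect_equal(got$dcs_depth, want$dcs_depth)
    }
  }
})

test_that("adding support never removes a call; raising thresholds never adds one", {
  set.seed(72)
  ref <- rand_ref(200, seed = 94)
  p <- pipeline_params()
  base_set <- lapply(1:4, function(i)
    make_dcs("chr1", 40L, with_subs(substr(ref, 41, 140), 50)))
  al <- align_dcs(base_set, ref)
  before <- call_snvs(al, ref, p)
  # one more supporting molecule
  al2 <- align_dcs(c(base_set,
                     list(make_dcs("chr1", 40L,
                                   with_subs(substr(ref, 41, 140), 50)))), ref)
  after <- call_snvs(al2, ref, p)
  expect_true(all(paste(before$pos, before$alt) %in%
                    paste(after$pos, after$alt)))
  # stricter support threshold
  stricter <- call_snvs(al, ref, pipeline_params(min_supporting_dcs = 5L))
  expect_true(all(paste(stricter$pos, stricter$alt) %in%
                    paste(before$pos, before$alt)))
  expect_equal(nrow(stricter), 0L)
})

test_that("indels aggregate after left-normalization with the 3-DCS floor", {
  p <- pipeline_params()
  # reference with a homopolymer to exercise normalization
  set.seed(12)
  left <- rand_seq(60); right <- rand_seq(60)
  refstr <- paste0(left, "AAAAAA", right)
  ref <- stats::setNames(refstr, "chr1")

  del_dcs <- function(del_at, start = 40L, len = 80L) {
    # deletion of 2 bases at 0-based ref position del_at, inside the read
    pre <- del_at - start
    cig <- paste0(pre, "M2D", len - pre, "M")
    bases <- paste0(substr(refstr, start + 1, del_at),
                    substr(refstr, del_at + 3, start + len + 2))
    make_dcs("chr1", start, bases, cigar = cig)
  }
  # the same physical deletion written at two offsets in the A-run
  d1 <- lapply(1:2, function(i) del_dcs(60L))
  d2 <- del_dcs(62L)
  calls <- call_indels(align_dcs(c(d1, list(d2)), ref), ref, p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$supporting_dcs, 3L)
  expect_equal(calls$kind, "deletion")
  # left-aligned anchor from the exhaustive-shift oracle
  o <- oracle_left_align(refstr, "deletion", 60, 2)
  expect_equal(calls$pos, o$p0)        # anchor base, 1-based == p0 (0-based)+1-1
  # two supporting DCSs are below the floor
  calls2 <- call_indels(align_dcs(d1, ref), ref, p)
  expect_equal(nrow(calls2), 0L)

  # insertions: 3 identical insertions emitted with anchored VCF fields
  ins_dcs <- function(start = 40L) {
    cig <- "20M3I60M"
    bases <- paste0(substr(refstr, start + 1, start + 20), "CAT",
                    substr(refstr, start + 21, start + 80))
    make_dcs("chr1", start, bases, cigar = cig)
  }
  ic <- call_indels(align_dcs(lapply(1:3, function(i) ins_dcs()), ref), ref, p)
  expect_equal(nrow(ic), 1L)
  expect_equal(ic$kind, "insertion")
  expect_equal(nchar(ic$alt) - nchar(ic$ref), 3L)
})

test_that("copy-number ratios use median depths with a strict log2 threshold", {
  p <- pipeline_params()
  eq <- list(r1 = rep(50, 100), r2 = rep(50, 100), r3 = rep(50, 100))
  cn <- call_cnv(eq, p)
  expect_true(all(cn$log2_ratio == 0))
  expect_false(any(cn$amplified))

  # exactly 2x the panel median: log2 = 1, NOT amplified (strict)
  two <- list(r1 = rep(100, 100), r2 = rep(50, 100), r3 = rep(50, 100))
  cn <- call_cnv(two, p)
  expect_equal(cn$log2_ratio[cn$region == "r1"], 1)
  expect_false(cn$amplified[cn$region == "r1"])

  four <- list(r1 = rep(200, 100), r2 = rep(50, 100), r3 = rep(50, 100))
  cn <- call_cnv(four, p)
  expect_equal(cn$log2_ratio[cn$region == "r1"], 2)
  expect_true(cn$amplified[cn$region == "r1"])

  expect_error(call_cnv(list(r1 = rep(5, 10)), p), "at least two")
  expect_error(call_cnv(list(r1 = rep(0, 10), r2 = rep(0, 10)), p), "zero")
})

test_that("per-region depth extraction agrees with interval arithmetic", {
  ref <- rand_ref(300, seed = 95)
  dcss <- align_dcs(list(make_dcs("chr1", 10L, substr(ref, 11, 110)),
                         make_dcs("chr1", 60L, substr(ref, 61, 160))), ref)
  panel <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = c(1, 71), end = c(20, 90)))
  panel$name <- c("a", "b")
  d <- dcs_depth_by_region(dcss, panel)
  expect_equal(d$a, c(rep(0L, 10), rep(1L, 10)))
  expect_equal(d$b, rep(2L, 20))
})

test_that("SNP fingerprints genotype by allele fraction with no-call handling", {
  ref <- rand_ref(200, seed = 96)
  loci <- data.frame(contig = "chr1", pos = c(50L, 120L),
                     ref = substring(ref, c(50, 120), c(50, 120)),
                     alt = c("A", "C"), stringsAsFactors = FALSE)
  loci$alt <- ifelse(loci$alt == loci$ref, c("T", "G"), loci$alt)

  hom_alt_reads <- lapply(1:6, function(i) {
    s <- substr(ref, 41, 140)
    substr(s, 10, 10) <- loci$alt[1]   # position 50
    make_dcs("chr1", 40L, s)
  })
  fp <- snp_fingerprint(align_dcs(hom_alt_reads, ref), loci)
  expect_identical(fp$genotypes[1], "2")
  expect_identical(fp$genotypes[2], "0")   # covered, all reference
  expect_equal(fp$callable, 2L)
  expect_equal(fingerprint_concordance(fp, fp), 1)

  # heterozygous band
  het_reads <- c(hom_alt_reads[1:3],
                 lapply(1:3, function(i) make_dcs("chr1", 40L,
                                                  substr(ref, 41, 140))))
  fp_het <- snp_fingerprint(align_dcs(het_reads, ref), loci)
  expect_identical(fp_het$genotypes[1], "1")

  # no coverage: all no-call, concordance undefined
  fp0 <- snp_fingerprint(list(), loci)
  expect_identical(fp0$genotypes, c(".", "."))
  expect_message(cc <- fingerprint_concordance(fp0, fp0), "no mutually callable")
  expect_true(is.na(cc))

  expect_error(snp_fingerprint(list(), rbind(loci, loci[1, ])), "duplicated")
})

test_that("fingerprint concordance of unrelated samples matches Hardy-Weinberg", {
  # enumeration oracle at allele frequency one half:
  # P(equal genotype) = 0.25^2 + 0.5^2 + 0.25^2 = 0.375
  probs <- c(`0` = 0.25, `1` = 0.5, `2` = 0.25)
  expected <- sum(probs^2)
  expect_equal(expected, 0.375)

  set.seed(123)
  n <- 4000
  loci <- data.frame(contig = "chr1", pos = seq_len(n), ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  g1 <- sample(names(probs), n, TRUE, probs)
  g2 <- sample(names(probs), n, TRUE, probs)
  cc <- fingerprint_concordance(fingerprint_from_genotypes(loci, g1),
                                fingerprint_from_genotypes(loci, g2))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(cc - expected), 3 * se)
})
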