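# Fixtures are built in code; oracles are deliberately naive, loop-based
# re-implementations written independently of the package internals.

rand_ref <- function(len, seed, name = "chr1") {
  set.seed(seed)
  r <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  stats::setNames(r, name)
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force window scan: longest homopolymer run (N excluded) whose bases
# all lie within the first `window` positions
oracle_max_run <- function(seq, window) {
  ch <- strsplit(substr(seq, 1, window), "")[[1]]
  best <- 0
  for (i in seq_along(ch)) {
    if (ch[i] == "N") next
    run <- 1
    j <- i + 1
    while (j <= length(ch) && ch[j] == ch[i]) { run <- run + 1; j <- j + 1 }
    best <- max(best, run)
  }
  best
}

# position-by-position consensus by explicit counting with table()
oracle_sscs <- function(seqs, consensus_fraction = 0.70, max_n_fraction = 0.30) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  out <- character(L)
  for (j in seq_len(L)) {
    col <- substr(seqs, j, j)
    nN <- sum(col == "N")
    if (nN / n > max_n_fraction + 1e-12) { out[j] <- "N"; next }
    tab <- table(factor(col[col != "N"], levels = c("A", "C", "G", "T")))
    if (!sum(tab)) { out[j] <- "N"; next }
    win <- names(tab)[which.max(tab)]
    out[j] <- if (max(tab) / n >= consensus_fraction - 1e-12) win else "N"
  }
  paste(out, collapse = "")
}

oracle_dcs <- function(b1, b2) {
  c1 <- strsplit(b1, "")[[1]]; c2 <- strsplit(b2, "")[[1]]
  paste(ifelse(c1 == c2 & c1 != "N", c1, "N"), collapse = "")
}

# sort-and-scan family partition oracle over (tag, contig, start, end, strand)
oracle_group <- function(reads) {
  key <- paste(reads$merged_tag, reads$contig, reads$start, reads$end,
               reads$strand)
  ord <- order(key)
  sizes <- integer(0)
  prev <- NULL; cur <- 0
  for (i in ord) {
    if (!identical(key[i], prev)) {
      if (cur > 0) sizes <- c(sizes, cur)
      cur <- 0; prev <- key[i]
    }
    cur <- cur + 1
  }
  if (cur > 0) sizes <- c(sizes, cur)
  sort(sizes)
}

# exhaustive left-shift of an indel against a reference string
oracle_left_align <- function(refstr, kind, p0, payload) {
  repeat {
    if (kind == "deletion") {
      k <- payload
      if (p0 > 0 &&
          substr(refstr, p0, p0) == substr(refstr, p0 + k, p0 + k)) {
        p0 <- p0 - 1
      } else break
    } else {
      k <- nchar(payload)
      if (p0 > 0 && substr(refstr, p0, p0) == substr(payload, k, k)) {
        payload <- paste0(substr(refstr, p0, p0), substr(payload, 1, k - 1))
        p0 <- p0 - 1
      } else break
    }
  }
  list(p0 = p0, payload = payload)
}

# brute-force SNV pileup over simple all-M aligned DCS records
oracle_snv_pileup <- function(dcss, reference, min_supp = 3, min_depth = 3,
                              w = 5) {
  refstr <- reference[[1]]
  contig <- names(reference)[1]
  calls <- list()
  for (pos in seq_len(nchar(refstr))) {
    refb <- substr(refstr, pos, pos)
    depth <- 0
    support <- list()
    outside <- list()
    for (i in seq_along(dcss)) {
      d <- dcss[[i]]
      L <- nchar(d$bases)
      off <- pos - 1 - d$start            # 0-based read offset
      if (off < 0 || off >= L) next
      depth <- depth + 1
      b <- substr(d$bases, off + 1, off + 1)
      if (b != refb && b != "N") {
        support[[b]] <- c(support[[b]], i)
        if (off >= w && off < L - w)
          outside[[b]] <- c(outside[[b]], i)
      }
    }
    for (b in names(support)) {
      supp <- length(unique(support[[b]]))
      if (supp >= min_supp && depth >= min_depth &&
          length(outside[[b]]) > 0) {
        calls[[length(calls) + 1]] <- data.frame(
          contig = contig, pos = pos, ref = refb, alt = b,
          supporting_dcs = supp, dcs_depth = depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      supporting_dcs = integer(0), dcs_depth = integer(0)))
  out <- do.call(rbind, calls)
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

# hand-build a dcs record (read space equals reference orientation, '+')
make_dcs <- function(contig, start, bases, tag = NULL, quals = NULL,
                     strand = "+", cigar = NULL) {
  if (is.null(tag)) tag <- paste0(rand_seq(12), rand_seq(12))
  structure(list(
    tag_pair = c(tag, duplexct:::.transpose_tag(tag)),
    contig = contig, start = start, end = start + nchar(bases),
    strand = strand,
    cigar = if (is.null(cigar)) paste0(nchar(bases), "M") else cigar,
    bases = bases,
    quals = if (is.null(quals)) rep(37L, nchar(bases)) else quals,
    n_fraction = mean(strsplit(bases, "")[[1]] == "N"),
    member_counts = c(2L, 2L),
    sources = c("a", "b")
  ), class = "dcs")
}

# hand-build an sscs record
make_sscs <- function(tag, contig, start, bases, strand = "+",
                      quals = NULL, cigar = NULL) {
  structure(list(
    key = paste(tag, contig, start, strand, sep = "|"),
    merged_tag = tag, contig = contig, start = start,
    end = start + nchar(bases), strand = strand,
    cigar = if (is.null(cigar)) paste0(nchar(bases), "M") else cigar,
    bases = bases,
    quals = if (is.null(quals)) rep(37L, nchar(bases)) else quals,
    member_count = 2L, n_fraction = mean(strsplit(bases, "")[[1]] == "N")
  ), class = "sscs")
}

# per-base mismatch rate of a library against its error-free twin
# (same config and seed with the error process switched off)
library_error_rate <- function(cfg) {
  noerr_cfg <- cfg
  noerr_cfg$per_base_error_rate <- 0
  class(noerr_cfg) <- "sim_config"
  with_err <- simulate_duplex_library(cfg)
  no_err <- simulate_duplex_library(noerr_cfg)
  mm <- 0L; tot <- 0L
  for (k in c("r1", "r2")) {
    a <- strsplit(with_err[[k]]$seq, "")
    b <- strsplit(no_err[[k]]$seq, "")
    for (i in seq_along(a)) {
      real <- b[[i]] != "N"
      mm <- mm + sum(a[[i]][real] != b[[i]][real])
      tot <- tot + sum(real)
    }
  }
  list(mismatches = mm, bases = tot, rate = mm / tot)
}

# DCS-vs-reference mismatch rate over aligned, retained DCSs (all-M case)
dcs_error_rate <- function(retained, reference) {
  mm <- 0L; tot <- 0L
  for (d in retained) {
    refseg <- substr(reference[[d$contig]], d$start + 1, d$end)
    c1 <- strsplit(d$bases, "")[[1]]
    c2 <- strsplit(refseg, "")[[1]]
    use <- c1 != "N"
    mm <- mm + sum(c1[use] != c2[use])
    tot <- tot + sum(use)
  }
  list(mismatches = mm, bases = tot, rate = if (tot) mm / tot else 0)
}

# run the consensus stages (no calling) on a simulated library
consensus_stage <- function(cfg, params = pipeline_params()) {
  lib <- simulate_duplex_library(cfg)
  pre <- preprocess_pairs(lib$r1, lib$r2, anchor = cfg$anchor, params = params)
  placed <- placements_from_truth(pre$kept, lib$truth, params)
  grouped <- group_families(placed$reads, params)
  sscs <- build_all_sscs(grouped, params)
  duplex <- pair_and_build_dcs(sscs$sscs, params)
  aligned <- align_dcs(duplex$dcs, cfg$reference)
  filt <- filter_dcs(aligned, cfg$reference, params)
  list(lib = lib, pre = pre, placed = placed, grouped = grouped,
       sscs = sscs, duplex = duplex, retained = filt$retained)
}
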