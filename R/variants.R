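# Variant calling over aligned duplex consensus sequences: reference
# mismatch/quality filters, pileup SNV calling with supporting-molecule and
# head/tail-artifact filters, indel aggregation with left-normalization,
# focal copy-number log2 ratios, and the SNP identity fingerprint.

.ref_sub <- function(reference, contig, start0, end0) {
  substr(reference[[contig]], start0 + 1L, end0)
}

# walk a DCS's alignment, returning M segments as
# data.frame(ref_start0, read_start0, len)
.m_segments <- function(ops) {
  refp <- 0L; readp <- 0L
  segs <- list()
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]
    switch(ops$op[i],
      M = {
        segs[[length(segs) + 1L]] <- c(refp, readp, len)
        refp <- refp + len; readp <- readp + len
      },
      I = readp <- readp + len,
      D = refp <- refp + len)
  }
  if (!length(segs))
    return(data.frame(ref_start0 = integer(0), read_start0 = integer(0),
                      len = integer(0)))
  m <- do.call(rbind, segs)
  data.frame(ref_start0 = m[, 1L], read_start0 = m[, 2L], len = m[, 3L])
}

#' Align duplex consensus sequences to the reference
#'
#' Converts DCS records to reference orientation (reverse-complementing
#' minus-strand consensi), attaches their alignment operations and counts
#' reference mismatches over aligned positions ('N' is undefined, not a
#' mismatch). A DCS extending past its contig end is rejected.
#'
#' @param dcs_list list of `dcs` records from [pair_and_build_dcs()].
#' @param reference named character vector of contigs.
#' @return list of `aligned_dcs` records with fields `id`, `contig`, `start`
#'   (0-based), `end`, `strand`, `cigar`, `ops`, `bases` (reference
#'   orientation), `quals`, `mismatches`.
#' @export
align_dcs <- function(dcs_list, reference) {
  if (!length(dcs_list)) return(list())
  ops_all <- lapply(dcs_list, function(d) .parse_cigar(d$cigar))
  rl_all <- vapply(ops_all, .cigar_read_len, 0L)
  # padding beyond the aligned fragment carries no alignment
  bases_all <- substr(vapply(dcs_list, `[[`, "", "bases"), 1L, rl_all)
  minus <- vapply(dcs_list, `[[`, "", "strand") == "-"
  if (any(minus)) bases_all[minus] <- .revcomp(bases_all[minus])
  lapply(seq_along(dcs_list), function(i) {
    d <- dcs_list[[i]]
    if (!d$contig %in% names(reference))
      stop("align_dcs: unknown contig ", d$contig)
    if (d$end > nchar(reference[[d$contig]]))
      stop("align_dcs: DCS extends past the end of contig ", d$contig)
    ops <- ops_all[[i]]
    rl <- rl_all[i]
    bases <- bases_all[i]
    quals <- d$quals[seq_len(rl)]
    if (minus[i]) quals <- rev(quals)
    mm <- 0L
    segs <- .m_segments(ops)
    for (k in seq_len(nrow(segs))) {
      rs <- .ref_sub(reference, d$contig, d$start + segs$ref_start0[k],
                     d$start + segs$ref_start0[k] + segs$len[k])
      bs <- substr(bases, segs$read_start0[k] + 1L,
                   segs$read_start0[k] + segs$len[k])
      b1 <- charToRaw(bs); b2 <- charToRaw(rs)
      mm <- mm + sum(b1 != b2 & b1 != charToRaw("N"))
    }
    structure(list(
      id = paste0(d$tag_pair[1L], "|", d$contig, ":", d$start, "-", d$end,
                  d$strand),
      contig = d$contig, start = d$start, end = d$end, strand = d$strand,
      cigar = d$cigar, ops = ops, bases = bases, quals = quals,
      mismatches = as.integer(mm)
    ), class = "aligned_dcs")
  })
}

#' Reference-mismatch and base-quality DCS filter
#'
#' Drops DCSs with strictly more than `max_dcs_mismatches` reference
#' mismatches; the count is taken before quality masking so that a damaged
#' low-quality molecule cannot evade the filter. Bases below `min_phred` in
#' retained DCSs are masked to 'N'.
#'
#' @param aligned list of `aligned_dcs` records.
#' @param reference named character vector of contigs.
#' @param params pipeline parameters.
#' @return list with `retained` and `dropped`
#'   (data frame `id`, `reason`, `mismatches`).
#' @export
filter_dcs <- function(aligned, reference, params = pipeline_params()) {
  drop <- list(); keep <- list()
  for (d in aligned) {
    if (d$mismatches > params$max_dcs_mismatches) {
      drop[[length(drop) + 1L]] <- data.frame(
        id = d$id, reason = "too_many_mismatches", mismatches = d$mismatches,
        stringsAsFactors = FALSE)
      next
    }
    low <- which(d$quals < params$min_phred)
    if (length(low)) {
      ch <- strsplit(d$bases, "", fixed = TRUE)[[1L]]
      ch[low] <- "N"
      d$bases <- paste(ch, collapse = "")
    }
    keep[[length(keep) + 1L]] <- d
  }
  list(retained = keep,
       dropped = if (length(drop)) do.call(rbind, drop) else
         data.frame(id = character(0), reason = character(0),
                    mismatches = integer(0), stringsAsFactors = FALSE))
}

# coverage of reference position pos0 by M segments of the retained set;
# seg_tab as built in .dcs_obs
.depth_at <- function(seg_tab, contig, pos0) {
  sum(seg_tab$contig == contig & seg_tab$s <= pos0 & pos0 < seg_tab$e)
}

# mismatch observations and M-segment table over a retained DCS set
.dcs_obs <- function(retained, reference, params) {
  obs <- list(); segl <- list()
  w <- params$head_tail_window
  for (di in seq_along(retained)) {
    d <- retained[[di]]
    segs <- .m_segments(d$ops)
    rl <- .cigar_read_len(d$ops)
    for (k in seq_len(nrow(segs))) {
      s0 <- d$start + segs$ref_start0[k]
      segl[[length(segl) + 1L]] <- data.frame(
        contig = d$contig, s = s0, e = s0 + segs$len[k], dcs = di,
        stringsAsFactors = FALSE)
      rs <- .ref_sub(reference, d$contig, s0, s0 + segs$len[k])
      bs <- substr(d$bases, segs$read_start0[k] + 1L,
                   segs$read_start0[k] + segs$len[k])
      b1 <- charToRaw(bs); b2 <- charToRaw(rs)
      mi <- which(b1 != b2 & b1 != charToRaw("N"))
      if (length(mi)) {
        ro <- segs$read_start0[k] + mi - 1L   # 0-based read offset
        obs[[length(obs) + 1L]] <- data.frame(
          contig = d$contig, pos0 = s0 + mi - 1L,
          base = substring(bs, mi, mi), dcs = di,
          head_tail = ro < w | ro >= rl - w,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    obs = if (length(obs)) do.call(rbind, obs) else
      data.frame(contig = character(0), pos0 = integer(0), base = character(0),
                 dcs = integer(0), head_tail = logical(0)),
    segs = if (length(segl)) do.call(rbind, segl) else
      data.frame(contig = character(0), s = integer(0), e = integer(0),
                 dcs = integer(0))
  )
}

#' Call SNVs from retained duplex consensus sequences
#'
#' Pileup over the retained DCS set. A candidate is a position where at
#' least one DCS shows a non-reference, non-'N' base outside the head/tail
#' artifact window of its molecule. A candidate is emitted when it is
#' supported by at least `min_supporting_dcs` distinct DCSs at a DCS depth
#' of at least `min_dcs_depth`. The variant allele fraction is
#' supporting / depth.
#'
#' @param retained list of `aligned_dcs` records from [filter_dcs()].
#' @param reference named character vector of contigs.
#' @param params pipeline parameters.
#' @param verbose when `TRUE`, rejected candidates are also returned with a
#'   `filter` value in `head_tail | low_support | low_depth`.
#' @return data frame with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `kind`, `supporting_dcs`, `dcs_depth`, `vaf`, `filter`.
#' @export
call_snvs <- function(retained, reference, params = pipeline_params(),
                      verbose = FALSE) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), supporting_dcs = integer(0),
                      dcs_depth = integer(0), vaf = numeric(0),
                      filter = character(0), stringsAsFactors = FALSE)
  if (!length(retained)) return(empty)
  po <- .dcs_obs(retained, reference, params)
  if (!nrow(po$obs)) return(empty)
  key <- paste(po$obs$contig, po$obs$pos0, po$obs$base, sep = "|")
  rows <- lapply(split(seq_len(nrow(po$obs)), key), function(ii) {
    o <- po$obs[ii, , drop = FALSE]
    supp <- length(unique(o$dcs))
    depth <- .depth_at(po$segs, o$contig[1L], o$pos0[1L])
    filt <-
      if (all(o$head_tail)) "head_tail"
      else if (supp < params$min_supporting_dcs) "low_support"
      else if (depth < params$min_dcs_depth) "low_depth"
      else "PASS"
    data.frame(
      contig = o$contig[1L], pos = o$pos0[1L] + 1L,
      ref = .ref_sub(reference, o$contig[1L], o$pos0[1L], o$pos0[1L] + 1L),
      alt = o$base[1L], kind = "snv",
      supporting_dcs = supp, dcs_depth = depth, vaf = supp / depth,
      filter = filt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!verbose) out <- out[out$filter == "PASS", , drop = FALSE]
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# left-normalize one indel against the reference; kind "deletion" deletes
# ref[p0, p0+k) and kind "insertion" inserts seq before ref position p0
# (all 0-based); returns VCF-style (pos1, ref, alt)
.normalize_indel <- function(reference, contig, kind, p0, seq_or_len) {
  refstr <- reference[[contig]]
  base_at <- function(i0) substr(refstr, i0 + 1L, i0 + 1L)
  if (kind == "deletion") {
    k <- seq_or_len
    while (p0 > 0L && base_at(p0 - 1L) == base_at(p0 + k - 1L)) p0 <- p0 - 1L
    anchor <- max(p0 - 1L, 0L)
    list(pos = anchor + 1L,
         ref = substr(refstr, anchor + 1L, anchor + 1L + k),
         alt = base_at(anchor))
  } else {
    s <- seq_or_len
    k <- nchar(s)
    while (p0 > 0L && base_at(p0 - 1L) == substr(s, k, k)) {
      s <- paste0(base_at(p0 - 1L), substr(s, 1L, k - 1L))
      p0 <- p0 - 1L
    }
    anchor <- max(p0 - 1L, 0L)
    list(pos = anchor + 1L, ref = base_at(anchor),
         alt = paste0(base_at(anchor), s))
  }
}

#' Call short indels from retained duplex consensus sequences
#'
#' Insertions and deletions in the DCS alignments are left-normalized
#' against the reference, aggregated across DCSs, and emitted when
#' supported by at least `min_indel_dcs` altered DCSs.
#'
#' @inheritParams call_snvs
#' @return data frame in the same layout as [call_snvs()], `kind` in
#'   `insertion | deletion`.
#' @export
call_indels <- function(retained, reference, params = pipeline_params()) {
  recs <- list()
  for (di in seq_along(retained)) {
    d <- retained[[di]]
    refp <- d$start; readp <- 0L
    for (i in seq_len(nrow(d$ops))) {
      len <- d$ops$len[i]; op <- d$ops$op[i]
      if (op == "M") { refp <- refp + len; readp <- readp + len }
      else if (op == "D") {
        nv <- .normalize_indel(reference, d$contig, "deletion", refp, len)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = d$contig, pos = nv$pos, ref = nv$ref, alt = nv$alt,
          kind = "deletion", dcs = di, stringsAsFactors = FALSE)
        refp <- refp + len
      } else if (op == "I") {
        ins <- substr(d$bases, readp + 1L, readp + len)
        nv <- .normalize_indel(reference, d$contig, "insertion", refp, ins)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = d$contig, pos = nv$pos, ref = nv$ref, alt = nv$alt,
          kind = "insertion", dcs = di, stringsAsFactors = FALSE)
        readp <- readp + len
      }
    }
  }
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), supporting_dcs = integer(0),
                      dcs_depth = integer(0), vaf = numeric(0),
                      filter = character(0), stringsAsFactors = FALSE)
  if (!length(recs)) return(empty)
  recs <- do.call(rbind, recs)
  seg_tab <- .dcs_obs(retained, reference, params)$segs
  key <- paste(recs$contig, recs$pos, recs$ref, recs$alt, sep = "|")
  rows <- lapply(split(seq_len(nrow(recs)), key), function(ii) {
    r <- recs[ii, , drop = FALSE]
    supp <- length(unique(r$dcs))
    if (supp < params$min_indel_dcs) return(NULL)
    depth <- .depth_at(seg_tab, r$contig[1L], r$pos[1L] - 1L)
    data.frame(contig = r$contig[1L], pos = r$pos[1L], ref = r$ref[1L],
               alt = r$alt[1L], kind = r$kind[1L], supporting_dcs = supp,
               dcs_depth = depth, vaf = supp / max(depth, 1L),
               filter = "PASS", stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Focal copy-number calls from probe-region depths
#'
#' For each probe region the log2 ratio of the region's median per-base DCS
#' depth to the median per-base depth over all panel regions; a region is
#' amplified when the log2 ratio strictly exceeds the threshold (default 1).
#'
#' @param depth_by_region named list of non-negative per-base depth vectors,
#'   one per probe region; at least two regions are required and the panel
#'   median must be positive, otherwise the ratio is undefined.
#' @param params pipeline parameters.
#' @return data frame with columns `region`, `median_depth`, `panel_median`,
#'   `log2_ratio`, `amplified`.
#' @export
call_cnv <- function(depth_by_region, params = pipeline_params()) {
  if (length(depth_by_region) < 2L)
    stop("call_cnv: need at least two panel regions (ratio undefined)")
  if (any(vapply(depth_by_region, function(x) any(x < 0), TRUE)))
    stop("call_cnv: depths must be non-negative")
  panel_median <- stats::median(unlist(depth_by_region, use.names = FALSE))
  if (panel_median == 0)
    stop("call_cnv: panel-wide median depth is zero (ratio undefined)")
  med <- vapply(depth_by_region, stats::median, 0)
  lr <- log2(med / panel_median)
  data.frame(region = names(depth_by_region), median_depth = unname(med),
             panel_median = panel_median, log2_ratio = unname(lr),
             amplified = unname(lr > params$cnv_log2_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-base DCS depth over panel regions
#'
#' @param retained list of `aligned_dcs` records.
#' @param panel `GRanges` of panel regions with a `name` metadata column
#'   (as from [read_panel_bed()]).
#' @return named list of per-base integer depth vectors.
#' @export
dcs_depth_by_region <- function(retained, panel) {
  segs <- list()
  for (d in retained) {
    s <- .m_segments(d$ops)
    for (k in seq_len(nrow(s)))
      segs[[length(segs) + 1L]] <- c(d$contig, d$start + s$ref_start0[k],
                                     s$len[k])
  }
  gr <- if (length(segs)) {
    m <- do.call(rbind, segs)
    GenomicRanges::GRanges(m[, 1L],
                           IRanges::IRanges(start = as.integer(m[, 2L]) + 1L,
                                            width = as.integer(m[, 3L])))
  } else GenomicRanges::GRanges()
  cov <- GenomicRanges::coverage(gr)
  out <- list()
  for (i in seq_along(panel)) {
    ct <- as.character(GenomicRanges::seqnames(panel)[i])
    s <- GenomicRanges::start(panel)[i]; e <- GenomicRanges::end(panel)[i]
    v <- if (ct %in% names(cov)) {
      rl <- cov[[ct]]
      upto <- min(e, length(rl))
      got <- if (s <= upto) as.integer(rl[s:upto]) else integer(0)
      c(got, rep(0L, (e - s + 1L) - length(got)))
    } else rep(0L, e - s + 1L)
    out[[panel$name[i]]] <- as.integer(v)
  }
  out
}

#' SNP identity fingerprint from DCS allele fractions
#'
#' Genotypes each configured identity locus from the DCS pileup: with fewer
#' than 3 informative DCSs the locus is a no-call; an alt-allele fraction
#' below 0.15 is homozygous reference, above 0.85 homozygous alternate, and
#' heterozygous between. The identifier string concatenates the per-locus
#' codes (0/1/2, '.' for no-call) in locus order.
#'
#' @param retained list of `aligned_dcs` records.
#' @param loci data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`; duplicated loci are rejected.
#' @param params pipeline parameters.
#' @param het_low,het_high allele-fraction bounds of the heterozygous band.
#' @param min_depth informative-DCS depth below which a locus is a no-call.
#' @return object of class `snp_fingerprint` with `loci`, `genotypes`,
#'   `id_string`, `callable`.
#' @export
snp_fingerprint <- function(retained, loci, params = pipeline_params(),
                            het_low = 0.15, het_high = 0.85, min_depth = 3L) {
  if (anyDuplicated(paste(loci$contig, loci$pos)))
    stop("snp_fingerprint: duplicated identity loci")
  g <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    p0 <- loci$pos[i] - 1L
    nref <- 0L; nalt <- 0L
    for (d in retained) {
      if (d$contig != loci$contig[i]) next
      segs <- .m_segments(d$ops)
      for (k in seq_len(nrow(segs))) {
        s0 <- d$start + segs$ref_start0[k]
        if (s0 <= p0 && p0 < s0 + segs$len[k]) {
          off <- segs$read_start0[k] + (p0 - s0)
          b <- substr(d$bases, off + 1L, off + 1L)
          if (b == loci$ref[i]) nref <- nref + 1L
          else if (b == loci$alt[i]) nalt <- nalt + 1L
        }
      }
    }
    inf <- nref + nalt
    g[i] <- if (inf < min_depth) "."
      else {
        fr <- nalt / inf
        if (fr < het_low) "0" else if (fr > het_high) "2" else "1"
      }
  }
  structure(list(loci = loci, genotypes = g,
                 id_string = paste(g, collapse = ""),
                 callable = sum(g != ".")),
            class = "snp_fingerprint")
}

#' Build a fingerprint directly from genotype codes
#' @param loci identity locus table.
#' @param genotypes character vector of codes in `0 | 1 | 2 | .`.
#' @return `snp_fingerprint` object.
#' @export
fingerprint_from_genotypes <- function(loci, genotypes) {
  stopifnot(length(genotypes) == nrow(loci),
            all(genotypes %in% c("0", "1", "2", ".")))
  structure(list(loci = loci, genotypes = genotypes,
                 id_string = paste(genotypes, collapse = ""),
                 callable = sum(genotypes != ".")),
            class = "snp_fingerprint")
}

#' Fingerprint concordance
#'
#' Fraction of mutually callable loci with identical genotype. With no
#' mutually callable locus the concordance is undefined and reported as
#' `NA`.
#'
#' @param a,b `snp_fingerprint` objects over the same locus set.
#' @return concordance in \[0, 1\], or `NA` when undefined.
#' @export
fingerprint_concordance <- function(a, b) {
  stopifnot(inherits(a, "snp_fingerprint"), inherits(b, "snp_fingerprint"),
            length(a$genotypes) == length(b$genotypes))
  both <- a$genotypes != "." & b$genotypes != "."
  if (!any(both)) {
    message("fingerprint_concordance: no mutually callable loci; undefined")
    return(NA_real_)
  }
  mean(a$genotypes[both] == b$genotypes[both])
}
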