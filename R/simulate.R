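#' Simulation configuration for a duplex-tagged read library
#'
#' Describes the library the simulator emits: double-stranded cfDNA-like
#' fragments drawn uniformly from a reference, each ligated with two random
#' 12-nt duplex tags (alpha at one end, beta at the other) behind an
#' invariant 5-bp anchor, amplified into per-strand read families, and
#' sequenced as 150-base paired-end reads with i.i.d. substitution errors.
#' Spiked variants are assigned to molecules Bernoulli(allele_fraction) so
#' the realized mutant-molecule fraction is known exactly.
#'
#' @param reference named character vector of contig sequences (A/C/G/T).
#' @param n_molecules number of original double-stranded fragments.
#' @param read_length sequenced read length (bases).
#' @param tag_length duplex tag length per mate.
#' @param anchor invariant ligation-site anchor sequence.
#' @param fragment_length fragment size in bases; the 167 default is the
#'   modal plasma cfDNA fragment size.
#' @param family_size list describing reads per strand per molecule:
#'   `list(dist = "poisson", mean = 4)` (Poisson, minimum 0) or
#'   `list(dist = "fixed", n = k)`.
#' @param per_base_error_rate i.i.d. substitution error probability per
#'   sequenced base, in \[0, 0.5).
#' @param coincident_error_rate probability per fragment base of a
#'   strand-coincident substitution (applied to the molecule itself, hence
#'   shared by both strands); models duplex-surviving artifacts and defaults
#'   to 0.
#' @param low_qual_rate probability per sequenced base of carrying a low
#'   quality score (`low_qual_phred`) instead of the default phred 37.
#' @param low_qual_phred the injected low quality score.
#' @param spiked_variants `NULL` or data frame with columns `contig`, `pos`
#'   (1-based), `ref`, `alt` (VCF-style strings, so indels use an anchor
#'   base), `af` (allele fraction in \[0, 1\]).
#' @param seed integer seed; identical configurations give byte-identical
#'   libraries.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(reference, n_molecules,
                       read_length = 150L, tag_length = 12L, anchor = "TGACT",
                       fragment_length = 167L,
                       family_size = list(dist = "poisson", mean = 4),
                       per_base_error_rate = 0,
                       coincident_error_rate = 0,
                       low_qual_rate = 0, low_qual_phred = 20L,
                       spiked_variants = NULL, seed = 1L) {
  if (length(reference) == 0L || is.null(names(reference)) ||
      any(!nzchar(names(reference))))
    stop("sim_config: reference must be a non-empty named character vector")
  if (any(grepl("[^ACGT]", reference)))
    stop("sim_config: reference may contain only A/C/G/T")
  if (n_molecules < 0L) stop("sim_config: n_molecules must be >= 0")
  if (per_base_error_rate < 0 || per_base_error_rate >= 0.5)
    stop("sim_config: per_base_error_rate must lie in [0, 0.5)")
  if (coincident_error_rate < 0 || coincident_error_rate >= 0.5)
    stop("sim_config: coincident_error_rate must lie in [0, 0.5)")
  if (low_qual_rate < 0 || low_qual_rate > 1)
    stop("sim_config: low_qual_rate must lie in [0, 1]")
  if (!is.null(spiked_variants) && nrow(spiked_variants)) {
    need <- c("contig", "pos", "ref", "alt", "af")
    if (!all(need %in% names(spiked_variants)))
      stop("sim_config: spiked_variants needs columns ",
           paste(need, collapse = ", "))
    for (i in seq_len(nrow(spiked_variants))) {
      v <- spiked_variants[i, ]
      if (is.na(v$af) || v$af < 0 || v$af > 1)
        stop("sim_config: allele_fraction must lie in [0, 1]")
      if (!v$contig %in% names(reference))
        stop("sim_config: variant contig '", v$contig, "' not in reference")
      clen <- nchar(reference[[v$contig]])
      if (v$pos < 1L || v$pos + nchar(v$ref) - 1L > clen)
        stop("sim_config: variant at ", v$contig, ":", v$pos,
             " lies outside the reference contig")
      have <- substr(reference[[v$contig]], v$pos, v$pos + nchar(v$ref) - 1L)
      if (have != v$ref)
        stop("sim_config: variant ref '", v$ref, "' does not match reference ('",
             have, "') at ", v$contig, ":", v$pos)
    }
  }
  structure(list(
    reference = reference, n_molecules = as.integer(n_molecules),
    read_length = as.integer(read_length), tag_length = as.integer(tag_length),
    anchor = anchor, fragment_length = as.integer(fragment_length),
    family_size = family_size,
    per_base_error_rate = per_base_error_rate,
    coincident_error_rate = coincident_error_rate,
    low_qual_rate = low_qual_rate, low_qual_phred = as.integer(low_qual_phred),
    spiked_variants = spiked_variants, seed = as.integer(seed)
  ), class = "sim_config")
}

.draw_family_sizes <- function(n, family_size) {
  if (n == 0L) return(integer(0))
  switch(family_size$dist,
    poisson = stats::rpois(n, family_size$mean),
    fixed = rep(as.integer(family_size$n), n),
    stop("sim_config: unknown family_size dist '", family_size$dist, "'"))
}

# substitute the bases of `strings` at (string index, 1-based offset) pairs
# with a uniformly drawn different base
.substitute_bases <- function(strings, at_string, at_pos) {
  if (!length(at_string)) return(strings)
  bases <- c("A", "C", "G", "T")
  off <- sample.int(3L, length(at_string), replace = TRUE)
  for (k in seq_along(at_string)) {
    i <- at_string[k]; p <- at_pos[k]
    cur <- substr(strings[i], p, p)
    code <- match(cur, bases)
    if (is.na(code)) next  # never substitute padding
    new <- bases[((code - 1L + off[k]) %% 4L) + 1L]
    substr(strings[i], p, p) <- new
  }
  strings
}

#' Simulate a duplex-tagged paired-end library with ground truth
#'
#' Emits R1/R2 read records plus a truth object recording every molecule's
#' placement, tag pair, carried variants and per-strand family sizes, and the
#' realized mutant-molecule fraction of each spiked variant. Read anatomy per
#' mate: 12-nt tag, 5-bp anchor, fragment sequence, 'N'-padded to the read
#' length. A pair from strand 1 carries tag alpha on mate 1 and beta on
#' mate 2 (merged tag alpha+beta); a strand-2 pair carries the transposed
#' combination. Tags are drawn uniformly over ACGT^12 and re-drawn when two
#' distinct molecules at the same locus would collide into one family.
#'
#' @param config a [sim_config()] object.
#' @return list with `r1` and `r2` (data frames `id`, `seq`, `qual`) and
#'   `truth` (list with `molecules`, `edits`, `variants`, `config`).
#' @export
simulate_duplex_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_molecules
  ref <- config$reference
  flen <- config$fragment_length
  empty <- function() {
    rd <- data.frame(id = character(0), seq = character(0), qual = character(0),
                     stringsAsFactors = FALSE)
    list(r1 = rd, r2 = rd,
         truth = list(molecules = data.frame(), edits = data.frame(),
                      variants = data.frame(), config = config))
  }
  usable <- nchar(ref) >= flen
  if (n == 0L) return(empty())
  if (!any(usable))
    stop("simulate_duplex_library: no contig is at least fragment_length long")

  # placements, uniform over valid fragment starts of usable contigs
  w <- ifelse(usable, nchar(ref) - flen + 1L, 0L)
  contig_idx <- sample.int(length(ref), n, replace = TRUE, prob = w)
  contig <- names(ref)[contig_idx]
  start0 <- vapply(contig_idx, function(i) sample.int(w[i], 1L) - 1L, 0L)

  # duplex tags, re-drawn on same-locus collisions (incl. palindromic pairs)
  ta <- .random_tags(n, config$tag_length)
  tb <- .random_tags(n, config$tag_length)
  repeat {
    k1 <- paste(contig, start0, ta, tb)
    k2 <- paste(contig, start0, tb, ta)
    m <- match(k1, k2)
    bad <- duplicated(k1) | duplicated(k2) | ta == tb |
      (!is.na(m) & m != seq_len(n))
    if (!any(bad)) break
    ta[bad] <- .random_tags(sum(bad), config$tag_length)
    tb[bad] <- .random_tags(sum(bad), config$tag_length)
  }

  # spiked variants -> per-molecule edits
  edits <- data.frame(mol = integer(0), frag_off0 = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  sv <- config$spiked_variants
  var_truth <- data.frame()
  if (!is.null(sv) && nrow(sv)) {
    for (i in seq_len(nrow(sv))) {
      v <- sv[i, ]
      pos0 <- v$pos - 1L
      ov <- which(contig == v$contig & start0 <= pos0 &
                    pos0 + nchar(v$ref) <= start0 + flen)
      carrier <- ov[stats::runif(length(ov)) < v$af]
      if (length(carrier))
        edits <- rbind(edits, data.frame(
          mol = carrier, frag_off0 = pos0 - start0[carrier],
          ref = v$ref, alt = v$alt, stringsAsFactors = FALSE))
      var_truth <- rbind(var_truth, data.frame(
        contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt, af = v$af,
        n_overlapping = length(ov), n_carriers = length(carrier),
        realized_fraction = if (length(ov)) length(carrier) / length(ov)
                            else NA_real_,
        stringsAsFactors = FALSE))
    }
  }

  # molecule (fragment) sequences with edits applied
  frag <- substring(ref[contig_idx], start0 + 1L, start0 + flen)
  if (nrow(edits)) {
    for (m in unique(edits$mol)) {
      em <- edits[edits$mol == m, , drop = FALSE]
      em <- em[order(em$frag_off0, decreasing = TRUE), , drop = FALSE]
      s <- frag[m]
      for (j in seq_len(nrow(em))) {
        a <- em$frag_off0[j]
        s <- paste0(substr(s, 1L, a), em$alt[j],
                    substr(s, a + nchar(em$ref[j]) + 1L, nchar(s)))
      }
      frag[m] <- s
    }
  }

  # strand-coincident errors live on the molecule itself
  if (config$coincident_error_rate > 0) {
    fl <- nchar(frag)
    ms <- rep.int(seq_len(n), fl)
    ps <- sequence(fl)
    hit <- stats::runif(length(ms)) < config$coincident_error_rate
    frag <- .substitute_bases(frag, ms[hit], ps[hit])
  }

  k1 <- .draw_family_sizes(n, config$family_size)
  k2 <- .draw_family_sizes(n, config$family_size)

  molecules <- data.frame(
    mol = seq_len(n), contig = contig, start = start0,
    frag_len_ref = flen, frag_len_seq = nchar(frag),
    tag_a = ta, tag_b = tb, n_reads_s1 = k1, n_reads_s2 = k2,
    stringsAsFactors = FALSE
  )
  truth <- list(molecules = molecules, edits = edits,
                variants = var_truth, config = config)

  mol_of <- c(rep.int(seq_len(n), k1), rep.int(seq_len(n), k2))
  strand <- c(rep.int(1L, sum(k1)), rep.int(2L, sum(k2)))
  repid <- c(sequence(k1), sequence(k2))
  if (!length(mol_of)) {
    out <- empty(); out$truth <- truth; return(out)
  }

  core_len <- config$read_length - config$tag_length - nchar(config$anchor)
  fwd <- substr(frag[mol_of], 1L, core_len)
  rev <- substr(.revcomp(frag[mol_of]), 1L, core_len)
  core1 <- ifelse(strand == 1L, fwd, rev)
  core2 <- ifelse(strand == 1L, rev, fwd)
  tag1 <- ifelse(strand == 1L, ta[mol_of], tb[mol_of])
  tag2 <- ifelse(strand == 1L, tb[mol_of], ta[mol_of])

  build_mate <- function(tag, core) {
    s <- paste0(tag, config$anchor, core)
    pad <- config$read_length - nchar(s)
    paste0(s, strrep("N", pad))
  }
  seq1 <- build_mate(tag1, core1)
  seq2 <- build_mate(tag2, core2)

  nr <- length(seq1)
  L <- config$read_length
  apply_errors_and_qual <- function(seqs) {
    ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                 nrow = nr, byrow = TRUE)
    real <- ch != "N"
    if (config$per_base_error_rate > 0) {
      hit <- real & matrix(stats::runif(nr * L) < config$per_base_error_rate,
                           nrow = nr)
      idx <- which(hit)
      if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        code <- match(ch[idx], bases)
        off <- sample.int(3L, length(idx), replace = TRUE)
        ch[idx] <- bases[((code - 1L + off) %% 4L) + 1L]
      }
    }
    qm <- matrix("!", nrow = nr, ncol = L)
    qm[real] <- intToUtf8(37L + 33L, multiple = TRUE)
    if (config$low_qual_rate > 0) {
      lowc <- intToUtf8(config$low_qual_phred + 33L, multiple = TRUE)
      low <- real & matrix(stats::runif(nr * L) < config$low_qual_rate,
                           nrow = nr)
      qm[low] <- lowc
    }
    list(seq = do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE)),
         qual = do.call(paste0, as.data.frame(qm, stringsAsFactors = FALSE)))
  }
  m1 <- apply_errors_and_qual(seq1)
  m2 <- apply_errors_and_qual(seq2)

  ids <- sprintf("M%06d:S%d:%d", mol_of, strand, repid)
  list(
    r1 = data.frame(id = ids, seq = m1$seq, qual = m1$qual,
                    stringsAsFactors = FALSE),
    r2 = data.frame(id = ids, seq = m2$seq, qual = m2$qual,
                    stringsAsFactors = FALSE),
    truth = truth
  )
}

#' Simulate droplet digital PCR event counts
#'
#' Mutant droplet events are binomial in the true fractional abundance;
#' wild-type events are the remainder.
#'
#' @param true_fa_percent true fractional abundance in percent, \[0, 100\].
#' @param total_events total droplet events (>= 0).
#' @param seed integer seed.
#' @return data frame with columns `n_mut`, `n_wt`.
#' @export
simulate_ddpcr_counts <- function(true_fa_percent, total_events, seed = 1L) {
  if (is.na(true_fa_percent) || true_fa_percent < 0 || true_fa_percent > 100)
    stop("simulate_ddpcr_counts: true_fa_percent must lie in [0, 100]")
  if (is.na(total_events) || total_events < 0)
    stop("simulate_ddpcr_counts: total_events must be >= 0")
  set.seed(seed)
  n_mut <- stats::rbinom(1L, as.integer(total_events), true_fa_percent / 100)
  data.frame(n_mut = n_mut, n_wt = as.integer(total_events) - n_mut)
}

#' Write simulated truth tables
#'
#' Writes the per-molecule table and per-variant realized fractions as TSV,
#' plus a JSON sidecar with the headline simulation facts.
#'
#' @param truth the `truth` element of [simulate_duplex_library()] output.
#' @param prefix output path prefix; files `<prefix>.molecules.tsv`,
#'   `<prefix>.variants.tsv`, `<prefix>.json` are written.
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, prefix) {
  pm <- paste0(prefix, ".molecules.tsv")
  pv <- paste0(prefix, ".variants.tsv")
  pj <- paste0(prefix, ".json")
  utils::write.table(truth$molecules, pm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$variants, pv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(
    n_molecules = nrow(truth$molecules),
    n_read_pairs = if (nrow(truth$molecules))
      sum(truth$molecules$n_reads_s1 + truth$molecules$n_reads_s2) else 0L,
    seed = truth$config$seed,
    variants = truth$variants
  )
  jsonlite::write_json(side, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(pm, pv, pj))
}

#' Read a simulated truth molecule table
#' @param prefix the prefix used by [write_truth()].
#' @return list with `molecules` and `variants` data frames.
#' @export
read_truth <- function(prefix) {
  list(
    molecules = utils::read.delim(paste0(prefix, ".molecules.tsv"),
                                  stringsAsFactors = FALSE),
    variants = utils::read.delim(paste0(prefix, ".variants.tsv"),
                                 stringsAsFactors = FALSE)
  )
}

#' Serialize / load a simulation configuration as YAML
#' @param config a [sim_config()] object.
#' @param path YAML file path.
#' @return `write_sim_config` returns the path invisibly; `read_sim_config`
#'   returns a `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$reference <- as.list(x$reference)
  if (!is.null(x$spiked_variants))
    x$spiked_variants <- lapply(seq_len(nrow(x$spiked_variants)),
                                function(i) as.list(x$spiked_variants[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$reference <- unlist(x$reference)
  if (!is.null(x$spiked_variants))
    x$spiked_variants <- do.call(rbind, lapply(x$spiked_variants, as.data.frame))
  do.call(sim_config, x)
}
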