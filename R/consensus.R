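# Consensus assembly: tagged read pairs -> tag families -> single-strand
# consensus sequences (SSCS) -> duplex consensus sequences (DCS).
#
# Families are built per (merged 24-nt tag, reference interval, orientation)
# in read space: the two mates of a pair read the two ends of the fragment,
# and the complementary strand's opposite mate reads the same reference
# segment in the same orientation, so the transposed-tag family at an
# identical placement is the duplex partner.

# compose reference-orientation alignment ops for a whole fragment carrying
# VCF-style edits (anchored ref/alt); offsets are 0-based in the unedited
# fragment
.fragment_ops <- function(edits, frag_len_ref) {
  ops <- data.frame(len = integer(0), op = character(0))
  add <- function(len, op) {
    if (len > 0L) ops[nrow(ops) + 1L, ] <<- list(as.integer(len), op)
    invisible(NULL)
  }
  cur <- 0L
  if (nrow(edits)) {
    edits <- edits[order(edits$frag_off0), , drop = FALSE]
    for (i in seq_len(nrow(edits))) {
      a <- edits$frag_off0[i]
      nr <- nchar(edits$ref[i]); na <- nchar(edits$alt[i])
      add(a + 1L - cur, "M")                 # through the anchor base
      if (nr > na) add(nr - na, "D")
      if (na > nr) add(na - nr, "I")
      if (nr == na && nr > 1L) add(nr - 1L, "M")  # multi-base substitution
      cur <- a + nr
    }
  }
  add(frag_len_ref - cur, "M")
  ops
}

# prefix (side = "left") or suffix (side = "right") of an op list consuming
# exactly `read_bases` read bases; returns list(ops, ref_len)
.clip_ops <- function(ops, read_bases, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "right") ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
  out <- list(); need <- read_bases
  for (i in seq_len(nrow(ops))) {
    if (need == 0L) break
    len <- ops$len[i]; op <- ops$op[i]
    if (op == "D") { out[[length(out) + 1L]] <- c(len, op); next }
    take <- min(len, need)
    out[[length(out) + 1L]] <- c(take, op)
    need <- need - take
  }
  res <- data.frame(len = as.integer(vapply(out, `[`, "", 1L)),
                    op = vapply(out, `[`, "", 2L), stringsAsFactors = FALSE)
  # trailing deletions carry no read evidence
  while (nrow(res) && res$op[nrow(res)] == "D") res <- res[-nrow(res), , drop = FALSE]
  if (side == "right") res <- res[rev(seq_len(nrow(res))), , drop = FALSE]
  list(ops = res, ref_len = .cigar_ref_len(res), read_len = .cigar_read_len(res))
}

#' Derive read placements from simulation truth
#'
#' In self-contained mode the simulator's per-molecule truth supplies each
#' read's genomic placement (the external-aligner contract supplies it
#' otherwise). Each tagged pair yields two stranded reads: the mate reading
#' the fragment's left end in reference orientation (`+`) and the mate
#' reading the right end in reverse-complement orientation (`-`).
#'
#' @param tagged the `kept` data frame from [preprocess_pairs()].
#' @param truth the truth object from [simulate_duplex_library()].
#' @param params pipeline parameters.
#' @return list with `reads` (data frame `id`, `merged_tag`, `contig`,
#'   `start`, `end`, `strand`, `cigar`, `seq`, `qual`) and `unplaced`
#'   (data frame `read_id`, `reason`).
#' @export
placements_from_truth <- function(tagged, truth, params = pipeline_params()) {
  mols <- truth$molecules
  m <- regmatches(tagged$id, regexec("^M([0-9]+):S([12]):", tagged$id))
  mol <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[2L]) else NA_integer_, 0L)
  strand12 <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3L]) else NA_integer_, 0L)
  idx <- match(mol, if (nrow(mols)) mols$mol else integer(0))
  bad <- is.na(idx)
  unplaced <- data.frame(read_id = tagged$id[bad],
                         reason = rep("no_placement", sum(bad)),
                         stringsAsFactors = FALSE)
  t2 <- tagged[!bad, , drop = FALSE]
  idx <- idx[!bad]; strand12 <- strand12[!bad]
  if (!nrow(t2)) {
    return(list(reads = data.frame(id = character(0), merged_tag = character(0),
                                   contig = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   cigar = character(0), seq = character(0),
                                   qual = character(0), stringsAsFactors = FALSE),
                unplaced = unplaced))
  }
  core_len <- nchar(t2$seq1[1L])

  # per-molecule left/right clip of the fragment alignment
  umol <- unique(idx)
  clip <- new.env(parent = emptyenv())
  for (u in umol) {
    mi <- mols[u, ]
    em <- truth$edits[truth$edits$mol == mi$mol, , drop = FALSE]
    cov <- min(core_len, mi$frag_len_seq)
    ops <- .fragment_ops(em, mi$frag_len_ref)
    lf <- .clip_ops(ops, cov, "left")
    rt <- .clip_ops(ops, cov, "right")
    assign(as.character(mi$mol), list(
      left = list(start = mi$start, end = mi$start + lf$ref_len,
                  cigar = .cigar_string(lf$ops)),
      right = list(start = mi$start + mi$frag_len_ref - rt$ref_len,
                   end = mi$start + mi$frag_len_ref,
                   cigar = .cigar_string(rt$ops))
    ), envir = clip)
  }
  one_side <- function(i, side) get(as.character(mols$mol[idx[i]]), envir = clip)[[side]]
  n <- nrow(t2)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    cl <- one_side(i, "left"); cr <- one_side(i, "right")
    contig <- mols$contig[idx[i]]
    # strand-1 pairs read left on mate 1; strand-2 pairs read left on mate 2
    left_seq <- if (strand12[i] == 1L) t2$seq1[i] else t2$seq2[i]
    left_qual <- if (strand12[i] == 1L) t2$qual1[i] else t2$qual2[i]
    right_seq <- if (strand12[i] == 1L) t2$seq2[i] else t2$seq1[i]
    right_qual <- if (strand12[i] == 1L) t2$qual2[i] else t2$qual1[i]
    rows[[2L * i - 1L]] <- list(id = t2$id[i], merged_tag = t2$merged_tag[i],
                                contig = contig, start = cl$start, end = cl$end,
                                strand = "+", cigar = cl$cigar,
                                seq = left_seq, qual = left_qual)
    rows[[2L * i]] <- list(id = t2$id[i], merged_tag = t2$merged_tag[i],
                           contig = contig, start = cr$start, end = cr$end,
                           strand = "-", cigar = cr$cigar,
                           seq = right_seq, qual = right_qual)
  }
  reads <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    merged_tag = vapply(rows, `[[`, "", "merged_tag"),
    contig = vapply(rows, `[[`, "", "contig"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    cigar = vapply(rows, `[[`, "", "cigar"),
    seq = vapply(rows, `[[`, "", "seq"),
    qual = vapply(rows, `[[`, "", "qual"),
    stringsAsFactors = FALSE
  )
  list(reads = reads, unplaced = unplaced)
}

#' Naive near-exact placement for synthetic references
#'
#' A deliberately simple stand-in for the external genome aligner, usable on
#' small synthetic references: each mate is placed by a unique match of its
#' sequence (forward or reverse-complement) tolerating up to `max_mismatch`
#' substitutions; reads without a unique hit are routed to the unplaced log.
#' No indel alignment is attempted.
#'
#' @param tagged the `kept` data frame from [preprocess_pairs()].
#' @param reference named character vector of contigs.
#' @param params pipeline parameters.
#' @param max_mismatch substitution tolerance per mate.
#' @return same shape as [placements_from_truth()].
#' @export
place_reads_naive <- function(tagged, reference, params = pipeline_params(),
                              max_mismatch = 2L) {
  rows <- list(); unpl <- character(0)
  find_unique <- function(core) {
    hits <- list()
    for (cn in names(reference)) {
      subj <- Biostrings::DNAString(reference[[cn]])
      for (st in c("+", "-")) {
        pat <- if (st == "+") core else .revcomp(core)
        mt <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
        for (k in seq_along(mt))
          hits[[length(hits) + 1L]] <- list(contig = cn,
                                            start = Biostrings::start(mt)[k] - 1L,
                                            end = Biostrings::end(mt)[k],
                                            strand = st)
      }
    }
    if (length(hits) == 1L) hits[[1L]] else NULL
  }
  for (i in seq_len(nrow(tagged))) {
    ok <- TRUE
    for (mate in 1:2) {
      s <- sub("N+$", "", tagged[[paste0("seq", mate)]][i])
      h <- if (nchar(s)) find_unique(s) else NULL
      if (is.null(h)) { ok <- FALSE; break }
      rows[[length(rows) + 1L]] <- data.frame(
        id = tagged$id[i], merged_tag = tagged$merged_tag[i],
        contig = h$contig, start = h$start, end = h$end, strand = h$strand,
        cigar = paste0(nchar(s), "M"),
        seq = s, qual = substr(tagged[[paste0("qual", mate)]][i], 1L, nchar(s)),
        stringsAsFactors = FALSE)
    }
    if (!ok) {
      rows <- rows[seq_len(length(rows) - (mate - 1L))]  # drop partial mate
      unpl <- c(unpl, tagged$id[i])
    }
  }
  list(reads = if (length(rows)) do.call(rbind, rows) else
         data.frame(id = character(0), merged_tag = character(0),
                    contig = character(0), start = integer(0), end = integer(0),
                    strand = character(0), cigar = character(0),
                    seq = character(0), qual = character(0),
                    stringsAsFactors = FALSE),
       unplaced = data.frame(read_id = unpl,
                             reason = rep("no_placement", length(unpl)),
                             stringsAsFactors = FALSE))
}

#' Group stranded reads into tag families
#'
#' Partitions placed reads by (merged tag, contig, interval, orientation).
#' Families below the minimum member count cannot form a consensus and are
#' logged as undersized; reads lacking a placement must be routed to the
#' unplaced log upstream and never reach this function.
#'
#' @param reads placed reads as produced by [placements_from_truth()] or
#'   [place_reads_naive()].
#' @param params pipeline parameters.
#' @return list with `families` (list of family records) and `undersized`
#'   (data frame `key`, `n_members`).
#' @export
group_families <- function(reads, params = pipeline_params()) {
  if (any(is.na(reads$start) | is.na(reads$contig)))
    stop("group_families: read without placement (route to the unplaced log)")
  key <- paste(reads$merged_tag, reads$contig, reads$start, reads$end,
               reads$strand, sep = "|")
  groups <- split(seq_len(nrow(reads)), key)
  fams <- list(); small <- list()
  for (k in names(groups)) {
    ii <- groups[[k]]
    if (length(ii) < params$min_family_members) {
      small[[length(small) + 1L]] <- data.frame(key = k,
                                                n_members = length(ii),
                                                stringsAsFactors = FALSE)
      next
    }
    i1 <- ii[1L]
    fams[[length(fams) + 1L]] <- list(
      key = k, merged_tag = reads$merged_tag[i1], contig = reads$contig[i1],
      start = reads$start[i1], end = reads$end[i1], strand = reads$strand[i1],
      cigar = reads$cigar[i1],
      seqs = reads$seq[ii], quals = reads$qual[ii], n = length(ii))
  }
  list(families = fams,
       undersized = if (length(small)) do.call(rbind, small) else
         data.frame(key = character(0), n_members = integer(0),
                    stringsAsFactors = FALSE))
}

#' Build a single-strand consensus sequence
#'
#' Position-by-position consensus over a tag family: the modal base is kept
#' when at least `consensus_fraction` (70%) of members carry it (inclusive);
#' otherwise the position is undefined ('N'). A position where strictly more
#' than `max_n_fraction` (30%) of members are 'N' is reported as 'N'
#' regardless. 'N' members count toward the member total but never toward a
#' base's coherence count. The consensus base's quality is the maximum member
#' quality of the winning base; undefined positions carry quality 0.
#'
#' @param family one family record from [group_families()].
#' @param params pipeline parameters.
#' @return an `sscs` record (list), or `NULL` when the family is below the
#'   minimum member count.
#' @export
build_sscs <- function(family, params = pipeline_params()) {
  n <- length(family$seqs)
  if (n < params$min_family_members) return(NULL)
  lens <- nchar(family$seqs)
  if (length(unique(lens)) != 1L)
    stop("build_sscs: family members of unequal length (upstream bug)")
  L <- lens[1L]
  ch <- matrix(unlist(strsplit(family$seqs, "", fixed = TRUE),
                      use.names = FALSE), nrow = n, byrow = TRUE)
  qm <- matrix(unlist(lapply(family$quals, .qual_to_int), use.names = FALSE),
               nrow = n, byrow = TRUE)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) colSums(ch == b),
                numeric(L))
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L,
                             dimnames = list(NULL, c("A", "C", "G", "T")))
  nN <- colSums(ch == "N")
  wi <- max.col(cnt, ties.method = "first")
  wc <- cnt[cbind(seq_len(L), wi)]
  winb <- c("A", "C", "G", "T")[wi]
  undef <- .more_than_frac(nN, n, params$max_n_fraction) |
    !.at_least_frac(wc, n, params$consensus_fraction)
  bases <- ifelse(undef, "N", winb)
  mask <- ch == matrix(bases, n, L, byrow = TRUE)
  qual <- Reduce(pmax, lapply(seq_len(n), function(i) ifelse(mask[i, ], qm[i, ], 0L)))
  qual[undef] <- 0L
  structure(list(
    key = family$key, merged_tag = family$merged_tag,
    contig = family$contig, start = family$start, end = family$end,
    strand = family$strand, cigar = family$cigar,
    bases = paste(bases, collapse = ""), quals = as.integer(qual),
    member_count = n, n_fraction = mean(bases == "N")
  ), class = "sscs")
}

#' Build all SSCSs for a family set
#'
#' @param grouped output of [group_families()].
#' @param params pipeline parameters.
#' @param strict_n when `TRUE`, SSCSs whose overall 'N' fraction strictly
#'   exceeds `max_n_fraction` are additionally discarded (the stricter
#'   reading of the single-strand N budget; the default applies the N rules
#'   per position and at the DCS level only).
#' @return list with `sscs` (list of `sscs` records), the pass-through
#'   `undersized` log, and `discarded_n` (data frame `key`, `n_fraction`).
#' @export
build_all_sscs <- function(grouped, params = pipeline_params(),
                           strict_n = FALSE) {
  sscs <- Filter(Negate(is.null),
                 lapply(grouped$families, build_sscs, params = params))
  discarded <- data.frame(key = character(0), n_fraction = numeric(0),
                          stringsAsFactors = FALSE)
  if (strict_n && length(sscs)) {
    nf <- vapply(sscs, `[[`, 0, "n_fraction")
    bad <- nf > params$max_n_fraction + 1e-9
    discarded <- data.frame(key = vapply(sscs[bad], `[[`, "", "key"),
                            n_fraction = nf[bad], stringsAsFactors = FALSE)
    sscs <- sscs[!bad]
  }
  list(sscs = sscs, undersized = grouped$undersized, discarded_n = discarded)
}

# transposed 24-nt tag: alpha+beta -> beta+alpha
.transpose_tag <- function(tag) {
  half <- nchar(tag) %/% 2L
  paste0(substr(tag, half + 1L, nchar(tag)), substr(tag, 1L, half))
}

#' Pair complementary SSCSs into duplex consensus sequences
#'
#' An SSCS with merged tag alpha+beta is paired with the SSCS carrying the
#' transposed tag beta+alpha at the identical placement (contig, interval,
#' orientation): these descend from the two strands of one original
#' molecule. Paired strands are compared position by position; matching
#' bases are kept, mismatches and positions undefined in either strand
#' become 'N'. A DCS whose 'N' fraction strictly exceeds `max_n_fraction`
#' (30%) is unsupported and discarded. Unpaired SSCSs (including
#' palindromic self-transposing tags) and ambiguous pairings are logged.
#' Each DCS base carries the minimum of the two strand qualities.
#'
#' @param sscs_list list of `sscs` records.
#' @param params pipeline parameters.
#' @return list with `dcs` (list of `dcs` records), `unpaired` (character
#'   keys), `ambiguous` (character keys) and `discarded` (data frame `key`,
#'   `n_fraction`).
#' @export
pair_and_build_dcs <- function(sscs_list, params = pipeline_params()) {
  n <- length(sscs_list)
  out <- list(); unpaired <- character(0); ambiguous <- character(0)
  discarded <- list()
  if (!n) return(list(dcs = out, unpaired = unpaired, ambiguous = ambiguous,
                      discarded = data.frame(key = character(0),
                                             n_fraction = numeric(0))))
  tag <- vapply(sscs_list, `[[`, "", "merged_tag")
  place <- vapply(sscs_list, function(s)
    paste(s$contig, s$start, s$end, s$strand, sep = "|"), "")
  fullkey <- paste(tag, place, sep = "|")
  partnerkey <- paste(vapply(tag, .transpose_tag, ""), place, sep = "|")
  done <- logical(n)
  # duplicate (tag, placement) keys cannot be paired unambiguously
  dup <- fullkey %in% fullkey[duplicated(fullkey)]
  if (any(dup)) {
    ambiguous <- c(ambiguous, vapply(sscs_list[dup], `[[`, "", "key"))
    done[dup] <- TRUE
  }
  pj <- match(partnerkey, fullkey)
  for (i in seq_len(n)) {
    if (done[i]) next
    if (tag[i] == .transpose_tag(tag[i])) {
      # palindromic tag: both strands collapse into one family, no duplex
      unpaired <- c(unpaired, sscs_list[[i]]$key); done[i] <- TRUE; next
    }
    j <- pj[i]
    if (is.na(j) || done[j]) {
      unpaired <- c(unpaired, sscs_list[[i]]$key); done[i] <- TRUE; next
    }
    a <- sscs_list[[i]]; b <- sscs_list[[j]]
    done[c(i, j)] <- TRUE
    if (nchar(a$bases) != nchar(b$bases) || a$cigar != b$cigar) {
      ambiguous <- c(ambiguous, a$key, b$key); next
    }
    r1 <- charToRaw(a$bases); r2 <- charToRaw(b$bases)
    keep <- r1 == r2 & r1 != charToRaw("N")
    rb <- r1; rb[!keep] <- charToRaw("N")
    quals <- pmin(a$quals, b$quals); quals[!keep] <- 0L
    nf <- mean(!keep)
    if (.more_than_frac(sum(!keep), length(keep), params$max_n_fraction)) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(key = paste(a$key, b$key, sep = " ~ "), n_fraction = nf,
                   stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      tag_pair = sort(c(a$merged_tag, b$merged_tag)),
      contig = a$contig, start = a$start, end = a$end, strand = a$strand,
      cigar = a$cigar, bases = rawToChar(rb), quals = as.integer(quals),
      n_fraction = nf, member_counts = c(a$member_count, b$member_count),
      sources = c(a$key, b$key)
    ), class = "dcs")
  }
  list(dcs = out, unpaired = unpaired, ambiguous = ambiguous,
       discarded = if (length(discarded)) do.call(rbind, discarded) else
         data.frame(key = character(0), n_fraction = numeric(0)))
}
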