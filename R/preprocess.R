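#' Pad a read to the uniform pipeline length
#'
#' Reads shorter than the uniform length are recovered by appending 'N'
#' bases (quality 0) at the end; longer reads indicate a platform or
#' configuration mismatch and are rejected.
#'
#' @param seq read sequence.
#' @param qual phred+33 quality string of the same length.
#' @param params pipeline parameters.
#' @return list with padded `seq` and `qual`.
#' @export
pad_read <- function(seq, qual, params = pipeline_params()) {
  L <- params$read_length
  n <- nchar(seq)
  if (nchar(qual) != n)
    stop("pad_read: sequence and quality lengths differ")
  if (n > L)
    stop("pad_read: read of length ", n, " exceeds the uniform length ", L,
         " (wrong platform or read_length configuration)")
  if (n == L) return(list(seq = seq, qual = qual))
  list(seq = paste0(seq, strrep(params$pad_base, L - n)),
       qual = paste0(qual, strrep("!", L - n)))
}

#' Leading-window homopolymer filter
#'
#' Drops a read pair when either mate's first `pre_homopolymer_window` bases
#' contain a single-base run strictly longer than `pre_homopolymer_len`.
#' Padding 'N's neither form nor extend a run.
#'
#' @param seq1,seq2 padded mate sequences.
#' @param params pipeline parameters.
#' @return list with `keep` (logical) and `reason` (`NA` or
#'   `"homopolymer"`).
#' @export
filter_homopolymer_reads <- function(seq1, seq2, params = pipeline_params()) {
  w <- params$pre_homopolymer_window
  bad <- .max_homopolymer_run(seq1, w) > params$pre_homopolymer_len ||
         .max_homopolymer_run(seq2, w) > params$pre_homopolymer_len
  list(keep = !bad, reason = if (bad) "homopolymer" else NA_character_)
}

#' Parse duplex tags off a read pair
#'
#' Each mate starts with the 12-nt duplex tag followed by the invariant 5-bp
#' ligation-site anchor. The anchor is matched exactly against the expected
#' sequence; pairs whose tag contains a homopolymer run strictly longer than
#' `tag_homopolymer_max` or whose anchor mismatches at any position are
#' discarded. On success the tag and anchor are removed from the stored
#' sequences and the two 12-nt tags are merged into a single 24-nt tag
#' (mate-1 tag first) that keys the read's molecule family.
#'
#' @param id read identifier.
#' @param seq1,qual1,seq2,qual2 padded mate sequences and qualities.
#' @param anchor the expected anchor sequence.
#' @param params pipeline parameters.
#' @return on keep, a list with `id`, stripped `seq1`/`qual1`/`seq2`/`qual2`,
#'   `tag_a`, `tag_b`, `merged_tag` and `keep = TRUE`; on drop, a list with
#'   `keep = FALSE` and `reason` in
#'   `malformed | tag_homopolymer | anchor_mismatch`.
#' @export
parse_tags <- function(id, seq1, qual1, seq2, qual2, anchor,
                       params = pipeline_params()) {
  tl <- params$tag_length
  al <- nchar(anchor)
  hdr <- tl + al
  if (nchar(seq1) < hdr || nchar(seq2) < hdr)
    return(list(keep = FALSE, reason = "malformed"))
  tag_a <- substr(seq1, 1L, tl)
  tag_b <- substr(seq2, 1L, tl)
  if (.max_homopolymer_run(tag_a) > params$tag_homopolymer_max ||
      .max_homopolymer_run(tag_b) > params$tag_homopolymer_max)
    return(list(keep = FALSE, reason = "tag_homopolymer"))
  if (substr(seq1, tl + 1L, hdr) != anchor ||
      substr(seq2, tl + 1L, hdr) != anchor)
    return(list(keep = FALSE, reason = "anchor_mismatch"))
  list(
    keep = TRUE, id = id,
    seq1 = substr(seq1, hdr + 1L, nchar(seq1)),
    qual1 = substr(qual1, hdr + 1L, nchar(qual1)),
    seq2 = substr(seq2, hdr + 1L, nchar(seq2)),
    qual2 = substr(qual2, hdr + 1L, nchar(qual2)),
    tag_a = tag_a, tag_b = tag_b, merged_tag = paste0(tag_a, tag_b)
  )
}

#' Pre-process a paired read library
#'
#' Runs the pre-processing stages in order over a library of read pairs:
#' length uniformization by 'N'-padding, the leading-window homopolymer
#' filter, and tag/anchor parsing. Unpaired reads cannot enter the duplex
#' workflow and are dropped with reason `unpaired` before pairing-dependent
#' stages. Every input pair is either emitted exactly once as a tagged pair
#' or appears exactly once in the drop log.
#'
#' @param r1,r2 data frames with columns `id`, `seq`, `qual` (mates matched
#'   by `id`).
#' @param anchor expected anchor sequence.
#' @param params pipeline parameters.
#' @return list with `kept` (data frame `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `tag_a`, `tag_b`, `merged_tag`, carrying attribute
#'   `tags_parsed = TRUE`), `drops` (data frame `read_id`, `reason`) and
#'   `counts` (named integer vector of stage tallies).
#' @export
preprocess_pairs <- function(r1, r2, anchor, params = pipeline_params()) {
  if (!is.null(attr(r1, "tags_parsed")) || !is.null(attr(r2, "tags_parsed")))
    stop("preprocess_pairs: input already tag-parsed; re-parsing is undefined")
  drops <- list()
  note_drop <- function(ids, reason) {
    if (length(ids))
      drops[[length(drops) + 1L]] <<- data.frame(read_id = ids, reason = reason,
                                                 stringsAsFactors = FALSE)
  }
  # mate pairing by id
  common <- intersect(r1$id, r2$id)
  note_drop(setdiff(c(r1$id, r2$id), common), "unpaired")
  i1 <- match(common, r1$id); i2 <- match(common, r2$id)
  p <- data.frame(id = common,
                  seq1 = r1$seq[i1], qual1 = r1$qual[i1],
                  seq2 = r2$seq[i2], qual2 = r2$qual[i2],
                  stringsAsFactors = FALSE)
  n_in <- max(length(r1$id), length(r2$id))

  if (nrow(p)) {
    # length uniformization (vectorized pad_read)
    L <- params$read_length
    over <- pmax(nchar(p$seq1), nchar(p$seq2)) > L
    if (any(over))
      stop("preprocess_pairs: read(s) longer than the uniform length ", L,
           " (e.g. ", p$id[which(over)[1L]], ")")
    p$qual1 <- paste0(p$qual1, strrep("!", L - nchar(p$seq1)))
    p$seq1 <- paste0(p$seq1, strrep(params$pad_base, L - nchar(p$seq1)))
    p$qual2 <- paste0(p$qual2, strrep("!", L - nchar(p$seq2)))
    p$seq2 <- paste0(p$seq2, strrep(params$pad_base, L - nchar(p$seq2)))

    hp <- vapply(seq_len(nrow(p)), function(i)
      filter_homopolymer_reads(p$seq1[i], p$seq2[i], params)$keep, TRUE)
    note_drop(p$id[!hp], "homopolymer")
    p <- p[hp, , drop = FALSE]
  }

  # tag/anchor parsing (vectorized parse_tags; drop precedence matches the
  # single-pair operation: malformed, tag homopolymer, anchor mismatch)
  tl <- params$tag_length
  hdr <- tl + nchar(anchor)
  malformed <- pmin(nchar(p$seq1), nchar(p$seq2)) < hdr
  tag_a <- substr(p$seq1, 1L, tl)
  tag_b <- substr(p$seq2, 1L, tl)
  tag_hp <- !malformed & (
    vapply(tag_a, .max_homopolymer_run, 0L, USE.NAMES = FALSE) >
      params$tag_homopolymer_max |
    vapply(tag_b, .max_homopolymer_run, 0L, USE.NAMES = FALSE) >
      params$tag_homopolymer_max)
  anch_bad <- !malformed & !tag_hp &
    (substr(p$seq1, tl + 1L, hdr) != anchor |
     substr(p$seq2, tl + 1L, hdr) != anchor)
  note_drop(p$id[malformed], "malformed")
  note_drop(p$id[tag_hp], "tag_homopolymer")
  note_drop(p$id[anch_bad], "anchor_mismatch")
  ok <- !(malformed | tag_hp | anch_bad)
  kept <- data.frame(
    id = p$id[ok],
    seq1 = substr(p$seq1[ok], hdr + 1L, nchar(p$seq1[ok])),
    qual1 = substr(p$qual1[ok], hdr + 1L, nchar(p$qual1[ok])),
    seq2 = substr(p$seq2[ok], hdr + 1L, nchar(p$seq2[ok])),
    qual2 = substr(p$qual2[ok], hdr + 1L, nchar(p$qual2[ok])),
    tag_a = tag_a[ok], tag_b = tag_b[ok],
    merged_tag = paste0(tag_a[ok], tag_b[ok]),
    stringsAsFactors = FALSE)
  attr(kept, "tags_parsed") <- TRUE
  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(read_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  counts <- c(pairs_in = n_in, kept = nrow(kept))
  for (rs in c("unpaired", "homopolymer", "malformed", "tag_homopolymer",
               "anchor_mismatch"))
    counts[paste0("dropped_", rs)] <- sum(drops$reason == rs)
  list(kept = kept, drops = drops, counts = counts)
}
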