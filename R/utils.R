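# Small DNA/string helpers shared across modules. Sequences are plain
# character vectors internally; Biostrings is used at the file-format
# boundary and for reverse complements.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# phred+33 string -> integer vector
.qual_to_int <- function(q) utf8ToInt(q) - 33L

# integer vector -> phred+33 string
.int_to_qual <- function(q) intToUtf8(pmax(0L, pmin(93L, as.integer(q))) + 33L)

# longest run of a single base within the first `window` bases; 'N' neither
# forms nor extends a run (padding is synthetic signal, not sequence).
.max_homopolymer_run <- function(seq, window = nchar(seq)) {
  s <- substr(seq, 1L, window)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!length(ch)) return(0L)
  r <- rle(ch)
  r$lengths[r$values == "N"] <- 0L
  max(r$lengths)
}

# draw n random tags of length len over {A,C,G,T}
.random_tags <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# parse a cigar string like "10M2D5M" into data.frame(len, op)
.parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MID]", cigar)[[1L]]
  if (m[1L] == -1L) stop("malformed cigar: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1L]]
  data.frame(len = as.integer(sub("[MID]$", "", toks)),
             op = sub("^[0-9]+", "", toks),
             stringsAsFactors = FALSE)
}

.cigar_string <- function(ops) {
  keep <- ops$len > 0L
  paste0(ops$len[keep], ops$op[keep], collapse = "")
}

# reference bases consumed by a cigar
.cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

# read bases consumed by a cigar
.cigar_read_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I")])

.round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}
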