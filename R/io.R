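# Readers and writers for the formats the pipeline touches: FASTQ (phred+33,
# gzip-optional), SAM consensus records, VCF 4.2 calls, panel BED, TSV logs
# and JSON reports.

#' Write paired reads as R1/R2 FASTQ
#'
#' @param lib list with `r1`, `r2` data frames (`id`, `seq`, `qual`), as from
#'   [simulate_duplex_library()].
#' @param prefix output prefix; `<prefix>_R1.fastq[.gz]` and
#'   `<prefix>_R2.fastq[.gz]` are written.
#' @param gz compress with gzip.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(lib, prefix, gz = FALSE) {
  ext <- if (gz) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (k in 1:2) {
    rd <- if (k == 1L) lib$r1 else lib$r2
    dna <- Biostrings::DNAStringSet(rd$seq)
    names(dna) <- rd$id
    Biostrings::writeXStringSet(dna, paths[k], format = "fastq",
                                qualities = Biostrings::BStringSet(rd$qual),
                                compress = gz)
  }
  invisible(paths)
}

#' Read one FASTQ file into a read data frame
#' @param path FASTQ path (gzip-transparent).
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("read_fastq: no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write tagged pairs as interleaved FASTQ
#'
#' The merged 24-nt tag is embedded in the read name after a `:UMI:` token;
#' mates carry `/1` and `/2` suffixes.
#'
#' @param tagged `kept` data frame from [preprocess_pairs()].
#' @param path output FASTQ path (`.gz` to compress).
#' @return invisibly, the path.
#' @export
write_tagged_fastq <- function(tagged, path) {
  n <- nrow(tagged)
  ids <- seqs <- quals <- character(2L * n)
  if (n) {
    base <- paste0(tagged$id, ":UMI:", tagged$merged_tag)
    ids[seq(1L, 2L * n, 2L)] <- paste0(base, "/1")
    ids[seq(2L, 2L * n, 2L)] <- paste0(base, "/2")
    seqs[seq(1L, 2L * n, 2L)] <- tagged$seq1
    seqs[seq(2L, 2L * n, 2L)] <- tagged$seq2
    quals[seq(1L, 2L * n, 2L)] <- tagged$qual1
    quals[seq(2L, 2L * n, 2L)] <- tagged$qual2
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write consensus sequences as SAM records
#'
#' One SAM line per consensus: the merged tag keys the read name, the
#' member count travels in the `cD:i:` auxiliary field. Minus-strand
#' consensi are written reference-oriented with flag 16.
#'
#' @param cons list of `sscs` or `dcs` records.
#' @param reference named character vector of contigs (for `@SQ` headers).
#' @param path output SAM path.
#' @return invisibly, the path.
#' @export
write_consensus_sam <- function(cons, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  lines <- vapply(cons, function(x) {
    tag <- if (!is.null(x[["merged_tag"]])) x[["merged_tag"]]
           else x[["tag_pair"]][1L]
    members <- if (!is.null(x[["member_count"]])) x[["member_count"]]
               else sum(x[["member_counts"]])
    bases <- x$bases; quals <- x$quals
    if (x$strand == "-") {
      bases <- .revcomp(bases)
      quals <- rev(quals)
    }
    flag <- if (x$strand == "-") 16L else 0L
    paste(tag, flag, x$contig, x$start + 1L, 60L, x$cigar, "*", 0L, 0L,
          bases, .int_to_qual(quals), paste0("cD:i:", members), sep = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read consensus SAM records
#'
#' Parses the SAM text written by [write_consensus_sam()] back into
#' consensus records (reference orientation retained as written).
#'
#' @param path SAM path.
#' @return list of records with fields `merged_tag`, `flag`, `contig`,
#'   `start` (0-based), `cigar`, `bases`, `quals`, `member_count`.
#' @export
read_consensus_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  lapply(ln, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("read_consensus_sam: malformed SAM line: ", l)
    aux <- f[-(1:11)]
    cd <- aux[startsWith(aux, "cD:i:")]
    list(merged_tag = f[1L], flag = as.integer(f[2L]), contig = f[3L],
         start = as.integer(f[4L]) - 1L, cigar = f[6L], bases = f[10L],
         quals = .qual_to_int(f[11L]),
         member_count = if (length(cd)) as.integer(sub("cD:i:", "", cd[1L]))
                        else NA_integer_)
  })
}

#' Write variant calls as VCF 4.2
#'
#' INFO carries the supporting-DCS count (`SUPP`), DCS depth (`DEPTH`) and
#' allele fraction (`VAF`, full precision so the file round-trips
#' losslessly); the FILTER column carries `PASS` or the rejection reason
#' when calls from a verbose run are written.
#'
#' @param calls data frame from [call_snvs()] / [call_indels()].
#' @param reference named character vector of contigs.
#' @param path output VCF path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(calls, reference, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Supporting DCS count\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"DCS depth at site\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"snv, insertion or deletion\">",
    "##FILTER=<ID=head_tail,Description=\"Evidence confined to DCS ends\">",
    "##FILTER=<ID=low_support,Description=\"Fewer supporting DCSs than required\">",
    "##FILTER=<ID=low_depth,Description=\"DCS depth below minimum\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tSUPP=%d;DEPTH=%d;VAF=%s;KIND=%s",
            calls$contig, calls$pos, calls$ref, calls$alt, calls$filter,
            calls$supporting_dcs, calls$dcs_depth,
            sprintf("%.17g", calls$vaf), calls$kind)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read VCF calls back into the call table layout
#' @param path VCF path.
#' @return data frame in the [call_snvs()] layout.
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), supporting_dcs = integer(0),
                      dcs_depth = integer(0), vaf = numeric(0),
                      filter = character(0), stringsAsFactors = FALSE))
  info1 <- function(k) sub(paste0(".*", k, "=([^;]*).*"), "\\1", fix$INFO)
  data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, kind = info1("KIND"),
    supporting_dcs = as.integer(info1("SUPP")),
    dcs_depth = as.integer(info1("DEPTH")),
    vaf = as.numeric(info1("VAF")),
    filter = fix$FILTER, stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a panel BED file
#'
#' Five-column BED: contig, 0-based half-open start/end, region name, role
#' (`hotspot`, `full_cds` or `snp_id`). Malformed records are reported with
#' their line number.
#'
#' @param path BED path.
#' @return `GRanges` (1-based closed, as usual for `GRanges`) with `name`
#'   and `role` metadata columns.
#' @export
read_panel_bed <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  rows <- lapply(seq_along(ln), function(i) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L)
      stop("read_panel_bed: line ", i, ": expected 5 columns, got ", length(f))
    s <- suppressWarnings(as.integer(f[2L])); e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop("read_panel_bed: line ", i, ": non-numeric interval")
    if (s >= e)
      stop("read_panel_bed: line ", i, ": start >= end (", s, " >= ", e, ")")
    if (!f[5L] %in% c("hotspot", "full_cds", "snp_id"))
      stop("read_panel_bed: line ", i, ": unknown role '", f[5L], "'")
    data.frame(contig = f[1L], start = s, end = e, name = f[4L], role = f[5L],
               stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(b$contig,
                               IRanges::IRanges(start = b$start + 1L,
                                                end = b$end))
  gr$name <- b$name
  gr$role <- b$role
  gr
}

#' Write a TSV drop/summary log
#' @param x data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_log_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#' @param report named list.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
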