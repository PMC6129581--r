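#' @importFrom stats pbinom rbinom runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement. IUPAC ambiguity codes are
#' complemented; case is preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                   "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguous bases are excluded from
#' both numerator and denominator.
#'
#' @param seq a single DNA string (non-empty).
#' @return fraction in \[0, 1\].
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  b <- seq_chars(toupper(seq))
  gc <- sum(b == "G" | b == "C")
  acgt <- sum(b %in% DNA_BASES)
  if (acgt == 0L) stop("sequence contains no unambiguous A/C/G/T bases")
  gc / acgt
}

# Phred+33 helpers ----------------------------------------------------------

phred_to_int <- function(qual) utf8ToInt(qual) - 33L

int_to_phred <- function(q) intToUtf8(q + 33L)

# per-base error probability from integer Phred scores
phred_error_prob <- function(q) 10^(-q / 10)

# FASTA / FASTQ IO (Biostrings) ---------------------------------------------

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping the package's internal
#' representation (named character vectors) at the boundary.
#'
#' @param file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read and write FASTQ (Phred+33)
#'
#' Reads are exchanged as a data.frame with columns `id`, `seq`, `qual`
#' (quality as a Phred+33 string), the package's read-set container.
#'
#' @param file path.
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @return `read_fastq` returns a read-set data.frame.
#' @export
read_fastq <- function(file) {
  # Biostrings warns about dropping its own internal metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, file) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, file)
  invisible(file)
}

# GFF3 ORF tables (rtracklayer) ----------------------------------------------

#' Read and write ORF annotations as GFF3
#'
#' ORF tables are data.frames with columns `contig`, `orf_id`, `start`,
#' `end` (1-based inclusive), `strand` ("+"/"-"), `product`, `class`.
#'
#' @param orfs ORF annotation data.frame.
#' @param file path.
#' @return `read_orf_gff3` returns an ORF data.frame.
#' @export
write_orf_gff3 <- function(orfs, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig,
    ranges = IRanges::IRanges(orfs$start, orfs$end),
    strand = orfs$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- orfs$orf_id
  gr$product <- orfs$product
  gr$orf_class <- if (is.null(orfs$class)) "unknown" else orfs$class
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' @rdname write_orf_gff3
#' @export
read_orf_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             orf_id = as.character(gr$ID),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             product = as.character(gr$product),
             class = if (is.null(gr$orf_class)) "unknown"
                     else as.character(gr$orf_class),
             stringsAsFactors = FALSE)
}

# Minimal SAM subset (single-segment, ungapped) -------------------------------

#' Read and write a minimal ungapped SAM subset
#'
#' Alignment records are exchanged as data.frames with columns `qname`,
#' `rname`, `pos` (1-based leftmost), `strand`, `seq`, `qual`. Only
#' single-segment ungapped records (CIGAR `<len>M`) are supported; headers
#' are written for the supplied reference lengths and skipped on read.
#'
#' @param aln alignment data.frame.
#' @param file path.
#' @param ref_lengths named integer vector of reference lengths.
#' @return `read_sam_ungapped` returns an alignment data.frame.
#' @export
write_sam_ungapped <- function(aln, file, ref_lengths) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (rn in names(ref_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, ref_lengths[[rn]]), con)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                     aln$qname, flag, aln$rname, aln$pos,
                     nchar(aln$seq), aln$seq, aln$qual), con)
  invisible(file)
}

#' @rdname write_sam_ungapped
#' @export
read_sam_ungapped <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, function(x) !grepl("^[0-9]+M$", x[6]), logical(1))
  if (any(bad)) stop("only ungapped records (CIGAR <len>M) are supported")
  data.frame(
    qname = vapply(f, `[`, "", 1L),
    rname = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    strand = ifelse(bitwAnd(as.integer(vapply(f, `[`, "", 2L)), 16L) > 0L,
                    "-", "+"),
    seq = vapply(f, `[`, "", 10L),
    qual = vapply(f, `[`, "", 11L),
    stringsAsFactors = FALSE)
}
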