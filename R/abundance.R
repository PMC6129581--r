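#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length_bp / 1000) * (total_reads / 1e6))`.
#'
#' @param count mapped read count for the feature.
#' @param length_bp feature length in bp (> 0).
#' @param total_reads total mapped reads in the library (> 0).
#' @return RPKM value.
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(count, length_bp, total_reads) {
  stopifnot(length_bp > 0, total_reads > 0, count >= 0)
  count / ((length_bp / 1000) * (total_reads / 1e6))
}

#' RPKM abundance profile for a set of features
#'
#' Counts reads recruited to each feature by exact shared k-mer (>= 31 nt
#' by default, either strand) and normalizes to RPKM; counts may also be
#' supplied directly.
#'
#' @param features named character vector of feature sequences, or a
#'   data.frame with `feature`, `length` when `counts` is given.
#' @param reads read-set data.frame or character vector of read
#'   sequences (ignored when `counts` is given).
#' @param total_reads total reads in the library.
#' @param counts optional named numeric vector of pre-computed counts.
#' @param min_kmer exact-match seed length.
#' @return data.frame: `feature`, `length`, `count`, `rpkm`.
#' @export
abundance_profile <- function(features, reads = NULL, total_reads,
                              counts = NULL, min_kmer = 31L) {
  if (is.null(counts)) {
    seqs <- if (is.data.frame(reads)) reads$seq else reads
    counts <- vapply(features, count_recruited, numeric(1),
                     read_seqs = seqs, k = min_kmer)
    lens <- nchar(features)
    ids <- names(features)
  } else if (is.data.frame(features)) {
    lens <- features$length
    ids <- features$feature
    counts <- counts[ids]
  } else {
    lens <- nchar(features)
    ids <- names(features)
    counts <- counts[ids]
  }
  data.frame(feature = ids, length = lens, count = as.numeric(counts),
             rpkm = mapply(rpkm, counts, lens,
                           MoreArgs = list(total_reads = total_reads)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Virus-to-host abundance ratio
#'
#' Fold difference between a viral feature's RPKM and a host marker
#' gene's RPKM in the same library (the host marker stands in for host
#' abundance, e.g. a RUBISCO gene for a cyanobacterial host).
#'
#' @param viral_rpkm viral feature RPKM.
#' @param marker_rpkm host marker RPKM.
#' @return the fold ratio, or `NA` (undefined) when the marker RPKM is 0.
#' @export
virus_host_ratio <- function(viral_rpkm, marker_rpkm) {
  if (marker_rpkm <= 0) return(NA_real_)
  viral_rpkm / marker_rpkm
}

#' DNA-to-RNA (abundance to activity) ratio
#'
#' Ratio of a feature's metagenomic RPKM to its metatranscriptomic RPKM;
#' low values indicate active transcription relative to copy number.
#'
#' @param dna_rpkm RPKM in the DNA (metagenome) channel.
#' @param rna_rpkm RPKM in the RNA (metatranscriptome) channel.
#' @return the ratio, or `NA` (undefined) when the RNA RPKM is 0.
#' @export
dna_rna_ratio <- function(dna_rpkm, rna_rpkm) {
  if (rna_rpkm <= 0) return(NA_real_)
  dna_rpkm / rna_rpkm
}

#' Log10 transform for abundance reporting
#'
#' Base-10 log used when plotting RPKM profiles; zeros are reported as
#' `NA` ("below detection") rather than `-Inf`.
#'
#' @param x RPKM values.
#' @return log10 values with zeros mapped to `NA`.
#' @export
log_rpkm <- function(x) ifelse(x > 0, log10(x), NA_real_)
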