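#' Quality-control parameters
#'
#' Defaults mirror a standard short-read cleanup for mat shotgun
#' libraries: keep only sequences longer than 30 bp, 3' trim bases below
#' Q28, hard-clip the first five bases, remove adapters on a perfect
#' match of at least 10 bp, and drop low-complexity reads with a DUST
#' score above 7.
#'
#' @param min_length minimum retained read length (bp).
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param clip5 number of 5' bases hard-clipped.
#' @param adapter adapter sequence; the shipped default is the Illumina
#'   TruSeq read-1 adapter.
#' @param adapter_min_overlap minimum perfect adapter overlap (bp).
#' @param dust_threshold DUST score threshold on the 0..100 scale.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_length = 30L, quality_cutoff = 28L, clip5 = 5L,
                      adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                      adapter_min_overlap = 10L, dust_threshold = 7) {
  stopifnot(min_length >= 1L, dust_threshold >= 0, dust_threshold <= 100,
            nzchar(adapter))
  structure(list(min_length = as.integer(min_length),
                 quality_cutoff = as.integer(quality_cutoff),
                 clip5 = as.integer(clip5), adapter = adapter,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 dust_threshold = dust_threshold),
            class = "qc_params")
}

#' Trim a 3' adapter by perfect prefix overlap
#'
#' Finds the leftmost position where a prefix of the adapter matches the
#' read perfectly over at least `min_overlap` bases in a region extending
#' to the read's 3' end (or containing the full adapter), and truncates
#' the read before it. Reads without such a match are returned unchanged.
#'
#' @param read list/row with `seq` and `qual` (or a plain string).
#' @param adapter adapter sequence.
#' @param min_overlap minimum perfect match length (bp).
#' @return the read with `seq`/`qual` truncated.
#' @export
trim_adapter <- function(read, adapter, min_overlap = 10L) {
  stopifnot(nzchar(adapter))
  plain <- is.character(read)
  s <- if (plain) read else read$seq
  L <- nchar(s)
  al <- nchar(adapter)
  cut <- -1L                     # -1: no match; otherwise keep s[1..cut]
  if (L >= min_overlap) {
    for (i in seq_len(L - min_overlap + 1L)) {
      k <- min(L - i + 1L, al)
      if (k >= min_overlap &&
          substr(s, i, i + k - 1L) == substr(adapter, 1L, k)) {
        cut <- i - 1L
        break
      }
    }
  }
  if (cut < 0L) return(read)
  if (plain) return(substr(s, 1L, cut))
  read$seq <- substr(s, 1L, cut)
  read$qual <- substr(read$qual, 1L, cut)
  read
}

#' 3' quality trimming by the partial-sum rule
#'
#' Scans from the 3' end accumulating `cutoff - q_i` and cuts at the
#' position where the running sum is maximal and positive (the BWA-style
#' rule). Reads whose qualities are all at or above the cutoff are
#' unchanged; ties are resolved toward trimming the least.
#'
#' @param read list/row with `seq` and `qual` (Phred+33 string).
#' @param cutoff Phred quality cutoff.
#' @return the read with the low-quality 3' suffix removed.
#' @export
quality_trim_3prime <- function(read, cutoff = 28L) {
  if (is.null(read$qual) || is.na(read$qual))
    stop("quality_trim_3prime requires per-base qualities")
  L <- nchar(read$seq)
  if (L == 0L) return(read)
  q <- phred_to_int(read$qual)
  d <- cutoff - q
  s <- rev(cumsum(rev(d)))        # s[j] = sum_{i=j..L} (cutoff - q_i)
  best <- max(s)
  if (best <= 0) return(read)
  j <- max(which(s == best))      # rightmost maximal cut point
  read$seq <- substr(read$seq, 1L, j - 1L)
  read$qual <- substr(read$qual, 1L, j - 1L)
  read
}

#' DUST low-complexity score
#'
#' Whole-read DUST score on a 0..100 scale: with `w` the read length and
#' `c_t` the counts of each overlapping 3-mer,
#' `score = 100 * sum(c_t * (c_t - 1) / 2) / ((w - 2) * (w - 3) / 2)`.
#' A homopolymer scores 100; a read whose triplets are all distinct
#' scores 0.
#'
#' @param seq a DNA string of length >= 3.
#' @return score in \[0, 100\].
#' @export
dust_score <- function(seq) {
  w <- nchar(seq)
  if (w < 3L) stop("dust_score requires a sequence of length >= 3")
  if (w < 4L) return(0)
  trip <- substring(seq, 1:(w - 2L), 3:w)
  ct <- table(trip)
  100 * sum(ct * (ct - 1) / 2) / ((w - 2) * (w - 3) / 2)
}

#' Read quality-control pipeline
#'
#' Applies, in order: adapter trimming, 3' quality trimming, 5' hard
#' clipping, a minimum-length filter, and a DUST low-complexity filter.
#' The report tallies reads removed by each rule; kept + removed equals
#' the input count.
#'
#' @param reads read-set data.frame (`id`, `seq`, `qual`).
#' @param params a [qc_params()].
#' @return list with `kept` (read-set data.frame) and `report` (named
#'   counts: input, removed_length, removed_dust, kept).
#' @export
qc_pipeline <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  n_in <- nrow(reads)
  keep <- logical(n_in)
  removed_length <- removed_dust <- 0L
  for (i in seq_len(n_in)) {
    r <- list(seq = reads$seq[i], qual = reads$qual[i])
    r <- trim_adapter(r, params$adapter, params$adapter_min_overlap)
    r <- quality_trim_3prime(r, params$quality_cutoff)
    if (params$clip5 > 0L) {
      r$seq <- substring(r$seq, params$clip5 + 1L)
      r$qual <- substring(r$qual, params$clip5 + 1L)
    }
    if (nchar(r$seq) < params$min_length) {
      removed_length <- removed_length + 1L
      next
    }
    if (nchar(r$seq) >= 4L && dust_score(r$seq) > params$dust_threshold) {
      removed_dust <- removed_dust + 1L
      next
    }
    keep[i] <- TRUE
    reads$seq[i] <- r$seq
    reads$qual[i] <- r$qual
  }
  kept <- reads[keep, , drop = FALSE]
  row.names(kept) <- NULL
  list(kept = kept,
       report = c(input = n_in, removed_length = removed_length,
                  removed_dust = removed_dust, kept = sum(keep)))
}
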