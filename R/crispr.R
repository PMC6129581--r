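#' CRISPR array detection parameters
#'
#' Length bounds and the three-repeat rule follow the published defaults
#' of standard repeat-spacer finders (repeats 23-55 bp, spacers 25-60 bp,
#' at least 3 repeat instances).
#'
#' @param repeat_bounds numeric length-2, repeat length bounds (bp).
#' @param spacer_bounds numeric length-2, spacer length bounds (bp).
#' @param min_repeats minimum repeat instances per array (>= 3).
#' @param max_repeat_mismatches tolerated mismatches per repeat instance
#'   against the consensus.
#' @return list of class `crispr_params`.
#' @export
crispr_params <- function(repeat_bounds = c(23L, 55L),
                          spacer_bounds = c(25L, 60L),
                          min_repeats = 3L, max_repeat_mismatches = 1L) {
  stopifnot(repeat_bounds[1] <= repeat_bounds[2],
            spacer_bounds[1] <= spacer_bounds[2], min_repeats >= 3L)
  structure(list(repeat_bounds = as.integer(repeat_bounds),
                 spacer_bounds = as.integer(spacer_bounds),
                 min_repeats = as.integer(min_repeats),
                 max_repeat_mismatches = as.integer(max_repeat_mismatches)),
            class = "crispr_params")
}

#' Detect CRISPR repeat-spacer arrays on a contig
#'
#' Seeds on exact k-mers (k = the repeat lower bound) recurring with a
#' spacing compatible with one repeat plus one spacer, extends each seeded
#' instance to the maximal unanimous repeat, and emits arrays with at
#' least `min_repeats` instances whose spacers fall within the length
#' bounds. Overlapping candidates are resolved by keeping the array with
#' more repeats (ties: leftmost).
#'
#' @param contig a DNA string (or named character vector of length 1).
#' @param params a [crispr_params()].
#' @param contig_id id recorded in the loci (defaults to the input name).
#' @return list of loci; each locus is a list with `locus_id`, `contig`,
#'   `repeat_consensus`, `repeat_intervals` (data.frame start/end) and
#'   `spacers` (data.frame id/seq/start/end).
#' @export
find_arrays <- function(contig, params = crispr_params(),
                        contig_id = NULL) {
  if (is.null(contig_id))
    contig_id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  s <- unname(contig)[1]
  L <- nchar(s)
  k <- params$repeat_bounds[1]
  if (L < 3L * k + 2L * params$spacer_bounds[1]) return(list())
  gap_min <- params$repeat_bounds[1] + params$spacer_bounds[1]
  gap_max <- params$repeat_bounds[2] + params$spacer_bounds[2]

  kmers <- substring(s, 1:(L - k + 1L), k:L)
  pos_by_kmer <- split(seq_len(L - k + 1L), kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= params$min_repeats]

  ch <- seq_chars(s)
  candidates <- list()
  for (pos in pos_by_kmer) {
    pos <- sort(pos)
    gaps <- diff(pos)
    ok <- gaps >= gap_min & gaps <= gap_max
    # maximal runs of seed positions with compatible spacing
    run_start <- 1L
    for (b in c(which(!ok), length(pos))) {
      run <- pos[run_start:b]
      run_start <- b + 1L
      if (length(run) < params$min_repeats) next
      candidates[[length(candidates) + 1L]] <-
        extend_array(ch, run, k, params)
    }
  }
  candidates <- candidates[!vapply(candidates, is.null, logical(1))]
  if (!length(candidates)) return(list())

  # dedupe/resolve overlaps: more repeats first, then leftmost
  span <- t(vapply(candidates, function(a)
    c(a$repeat_intervals$start[1], max(a$repeat_intervals$end)),
    numeric(2)))
  nrep <- vapply(candidates, function(a) nrow(a$repeat_intervals), integer(1))
  ord <- order(-nrep, span[, 1])
  accepted <- list()
  acc_span <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    overlaps <- nrow(acc_span) > 0 &&
      any(span[i, 1] <= acc_span[, 2] & span[i, 2] >= acc_span[, 1])
    if (overlaps) next
    accepted[[length(accepted) + 1L]] <- candidates[[i]]
    acc_span <- rbind(acc_span, span[i, ])
  }
  # order loci along the contig, assign ids and spacer ids
  ord2 <- order(vapply(accepted, function(a) a$repeat_intervals$start[1],
                       numeric(1)))
  loci <- accepted[ord2]
  for (i in seq_along(loci)) {
    loci[[i]]$locus_id <- sprintf("%s_CRISPR_%d", contig_id, i)
    loci[[i]]$contig <- contig_id
    nsp <- nrow(loci[[i]]$spacers)
    loci[[i]]$spacers$id <- sprintf("%s_spacer%d", loci[[i]]$locus_id,
                                    seq_len(nsp))
  }
  loci
}

# Extend seeded repeat instances (character vector ch, seed starts run,
# seed length k) to the maximal unanimous repeat; NULL if the resulting
# array violates the length bounds.
extend_array <- function(ch, run, k, params) {
  L <- length(ch)
  r <- length(run)
  rep_max <- params$repeat_bounds[2]
  # left extension
  el <- 0L
  repeat {
    idx <- run - el - 1L
    if (any(idx < 1L) || k + el >= rep_max) break
    if (length(unique(ch[idx])) > 1L) break
    # keep repeats clear of the previous instance's extension
    if (any(diff(run) <= k + el)) break
    el <- el + 1L
  }
  # right extension
  er <- 0L
  repeat {
    idx <- run + k + er
    if (any(idx > L) || k + el + er >= rep_max) break
    col <- ch[idx]
    if (length(unique(col)) > 1L) break
    if (any(diff(run) <= k + el + er + 1L)) break
    er <- er + 1L
  }
  starts <- run - el
  ends <- run + k + er - 1L
  rep_len <- k + el + er
  if (rep_len < params$repeat_bounds[1] || rep_len > rep_max) return(NULL)
  if (any(starts[-1] <= ends[-r])) return(NULL)   # overlapping repeats
  sp_start <- ends[-r] + 1L
  sp_end <- starts[-1] - 1L
  sp_len <- sp_end - sp_start + 1L
  if (any(sp_len < params$spacer_bounds[1] |
          sp_len > params$spacer_bounds[2])) return(NULL)
  consensus <- paste(ch[starts[1]:ends[1]], collapse = "")
  # every instance within the mismatch cap of the consensus (unanimous
  # extension makes this exact here; the cap guards future variants)
  spacers <- vapply(seq_len(r - 1L), function(i)
    paste(ch[sp_start[i]:sp_end[i]], collapse = ""), character(1))
  list(locus_id = NA_character_, contig = NA_character_,
       repeat_consensus = consensus,
       repeat_intervals = data.frame(start = starts, end = ends),
       spacers = data.frame(id = NA_character_, seq = spacers,
                            start = sp_start, end = sp_end,
                            stringsAsFactors = FALSE))
}

#' CRISPR locus transcriptional activity as RPKM
#'
#' Counts RNA reads sharing an exact match of at least `min_kmer` nt with
#' the locus sequence (either strand) and normalizes by locus length and
#' library size: `RPKM = count / (locus_kb * total_reads / 1e6)`.
#'
#' @param locus_seq the locus nucleotide sequence.
#' @param rna_reads read-set data.frame (`seq` column) or character
#'   vector of read sequences.
#' @param total_rna_reads total reads in the RNA library (> 0).
#' @param min_kmer exact-match seed length (default 31).
#' @return list with `count` and `rpkm`.
#' @export
locus_activity <- function(locus_seq, rna_reads, total_rna_reads,
                           min_kmer = 31L) {
  if (nchar(locus_seq) == 0L) stop("zero-length locus")
  stopifnot(total_rna_reads > 0)
  seqs <- if (is.data.frame(rna_reads)) rna_reads$seq else rna_reads
  count <- count_recruited(locus_seq, seqs, min_kmer)
  list(count = count,
       rpkm = rpkm(count, nchar(locus_seq), total_rna_reads))
}

# number of reads sharing an exact >= k nt match with feature (either
# strand), by k-mer set membership
count_recruited <- function(feature_seq, read_seqs, k = 31L) {
  fl <- nchar(feature_seq)
  if (fl < k) return(0L)
  fk <- substring(feature_seq, 1:(fl - k + 1L), k:fl)
  rc <- revcomp(feature_seq)
  fk <- unique(c(fk, substring(rc, 1:(fl - k + 1L), k:fl)))
  hits <- vapply(read_seqs, function(rs) {
    rl <- nchar(rs)
    if (rl < k) return(FALSE)
    any(substring(rs, 1:(rl - k + 1L), k:rl) %in% fk)
  }, logical(1), USE.NAMES = FALSE)
  sum(hits)
}
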