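#' Match a CRISPR spacer onto a viral genome
#'
#' Exhaustive end-to-end comparison of the spacer and its reverse
#' complement at every genome offset, reporting placements with at most
#' `max_mismatches` substitutions. Coordinates and mismatch positions are
#' always 1-based on the genome plus strand, so a spacer and its reverse
#' complement hit the same interval with opposite strand labels. For
#' circular genomes, placements wrapping the origin are included (wrapped
#' positions are reported modulo the genome length). An ambiguity base N
#' in the genome counts as a mismatch.
#'
#' @param spacer spacer sequence (A/C/G/T and IUPAC codes; non-IUPAC
#'   characters are an error).
#' @param genome a single genome string (or named character vector of
#'   length 1).
#' @param max_mismatches Hamming-distance cap (default 3).
#' @param circular include placements wrapping the origin.
#' @param report `"all-under-cap"` (every placement within the cap) or
#'   `"all-best"` (only placements at the minimum observed distance).
#' @return data.frame of hits: `spacer`, `target`, `start`, `end`,
#'   `strand`, `mismatches` (count), `mismatch_positions` (";"-joined
#'   plus-strand coordinates).
#' @export
match_spacer <- function(spacer, genome, max_mismatches = 3L,
                         circular = FALSE,
                         report = c("all-under-cap", "all-best")) {
  report <- match.arg(report)
  stopifnot(max_mismatches >= 0L)
  target <- if (!is.null(names(genome))) names(genome)[1] else "genome"
  gseq <- toupper(unname(genome)[1])
  sp <- toupper(spacer)
  if (grepl("[^ACGTRYSWKMBDHVN]", sp))
    stop("spacer contains non-IUPAC characters")
  m <- nchar(sp)
  L <- nchar(gseq)
  if (m > L) stop("spacer longer than genome")

  gext <- if (circular) paste0(gseq, substr(gseq, 1L, m - 1L)) else gseq
  gi <- utf8ToInt(gext)
  n_off <- nchar(gext) - m + 1L

  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") sp else revcomp(sp)
    qi <- utf8ToInt(q)
    # mm[o] = Hamming distance at offset o: sum over spacer positions of
    # (genome base != query base), vectorized one spacer-position at a time
    mm <- integer(n_off)
    for (j in seq_len(m))
      mm <- mm + (gi[j:(j + n_off - 1L)] != qi[j])
    ok <- which(mm <= max_mismatches)
    for (o in ok) {
      idx <- which(gi[o:(o + m - 1L)] != qi)
      gpos <- (o + idx - 2L) %% L + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        spacer = spacer, target = target,
        start = (o - 1L) %% L + 1L, end = (o + m - 2L) %% L + 1L,
        strand = strand, mismatches = mm[o],
        mismatch_positions = paste(gpos, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(spacer = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      mismatch_positions = character(0)))
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (report == "all-best") out <- out[out$mismatches == min(out$mismatches),
                                       , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Match a set of spacers onto a genome
#'
#' @param spacers named character vector of spacer sequences.
#' @param genome genome string (named character vector of length 1).
#' @param ... passed to [match_spacer()].
#' @return data.frame of hits with a leading `spacer_id` column.
#' @export
match_spacers <- function(spacers, genome, ...) {
  rows <- lapply(seq_along(spacers), function(i) {
    h <- match_spacer(spacers[[i]], genome, ...)
    if (nrow(h))
      cbind(spacer_id = names(spacers)[i] %||% sprintf("spacer%d", i), h,
            stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(spacer_id = character(0), spacer = character(0),
                      target = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0),
                      mismatch_positions = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
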