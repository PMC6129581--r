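#' Genome-screen parameters
#'
#' @param min_contig_len size floor (strictly over, bp) for circularity
#'   screening; dsDNA phage genomes in databases all exceed 5 kb.
#' @param min_terminal_overlap minimum exact terminal direct repeat (bp).
#' @param hallmark_terms viral hallmark product vocabulary
#'   (case-insensitive substring terms); defaults to the shipped list.
#' @return list of class `screen_params`.
#' @export
screen_params <- function(min_contig_len = 5000L, min_terminal_overlap = 20L,
                          hallmark_terms = load_hallmark_terms()) {
  stopifnot(min_terminal_overlap >= 10L)
  structure(list(min_contig_len = as.integer(min_contig_len),
                 min_terminal_overlap = as.integer(min_terminal_overlap),
                 hallmark_terms = hallmark_terms),
            class = "screen_params")
}

#' Load the shipped viral hallmark vocabulary
#'
#' @return character vector of product-name terms.
#' @export
load_hallmark_terms <- function() {
  path <- system.file("extdata", "hallmark_terms.txt", package = "virotope",
                      mustWork = TRUE)
  x <- readLines(path)
  x <- trimws(x[!startsWith(x, "#")])
  x[nzchar(x)]
}

#' Detect a circular contig by its terminal direct repeat
#'
#' A contig over the size floor is circular iff an exact terminal direct
#' repeat of at least `min_terminal_overlap` bp exists (its prefix equals
#' its suffix); the trimmed genome removes the duplicated suffix.
#'
#' @param contig a DNA string.
#' @param params a [screen_params()].
#' @return list with `is_circular`, `overlap` (repeat length, 0 if none)
#'   and `genome` (trimmed sequence if circular, else the input).
#' @export
detect_circular <- function(contig, params = screen_params()) {
  L <- nchar(contig)
  if (L <= params$min_contig_len)
    return(list(is_circular = FALSE, overlap = 0L, genome = contig))
  mo <- params$min_terminal_overlap
  anchor <- substr(contig, 1L, mo)
  occ <- gregexpr(anchor, contig, fixed = TRUE)[[1]]
  occ <- occ[occ > 1L]
  # candidate repeat lengths k = L - p + 1 for each anchor occurrence p,
  # longest first; cap at half the contig so prefix and suffix are disjoint
  best <- 0L
  for (p in occ) {
    k <- L - p + 1L
    if (k < mo || k > L %/% 2L) next
    if (substr(contig, p, L) == substr(contig, 1L, k)) {
      best <- k
      break   # occurrences scanned left to right: first valid is longest
    }
  }
  if (best >= mo)
    list(is_circular = TRUE, overlap = best,
         genome = substr(contig, 1L, L - best))
  else
    list(is_circular = FALSE, overlap = 0L, genome = contig)
}

#' Flag a contig carrying viral hallmark genes
#'
#' TRUE iff at least one ORF product matches a hallmark vocabulary term
#' (case-insensitive substring).
#'
#' @param orfs ORF data.frame for one contig (column `product`).
#' @param vocabulary character vector of hallmark terms.
#' @return logical.
#' @export
hallmark_flag <- function(orfs, vocabulary = load_hallmark_terms()) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(FALSE)
  prod <- tolower(orfs$product)
  any(vapply(tolower(vocabulary),
             function(v) any(grepl(v, prod, fixed = TRUE)), logical(1)))
}

#' Count strand switches along a genome
#'
#' Counts adjacent transcriptional-direction changes over the ORFs sorted
#' by start; a genome is two-clustered iff there is exactly one switch
#' (linearized at the origin).
#'
#' @param orfs ORF data.frame (columns `start`, `strand`), sorted by
#'   start.
#' @return list with `n_switches` and `is_two_cluster`.
#' @export
strand_clusters <- function(orfs) {
  if (nrow(orfs) < 2L)
    return(list(n_switches = 0L, is_two_cluster = FALSE))
  s <- orfs$strand[order(orfs$start)]
  n_sw <- sum(s[-1] != s[-length(s)])
  list(n_switches = n_sw, is_two_cluster = n_sw == 1L)
}

#' Screen contigs for circularity, hallmarks and organization
#'
#' @param contigs named character vector of contig sequences.
#' @param orfs ORF data.frame for all contigs (column `contig`).
#' @param params a [screen_params()].
#' @return data.frame: contig, length, circular, trimmed_length,
#'   hallmark, n_switches, two_cluster, gc.
#' @export
screen_contigs <- function(contigs, orfs = NULL, params = screen_params()) {
  rows <- lapply(names(contigs), function(id) {
    circ <- detect_circular(contigs[[id]], params)
    o <- if (is.null(orfs)) NULL else orfs[orfs$contig == id, , drop = FALSE]
    sw <- if (is.null(o) || nrow(o) == 0L)
      list(n_switches = NA_integer_, is_two_cluster = NA) else
      strand_clusters(o)
    data.frame(contig = id, length = nchar(contigs[[id]]),
               circular = circ$is_circular,
               trimmed_length = nchar(circ$genome),
               hallmark = hallmark_flag(o, params$hallmark_terms),
               n_switches = sw$n_switches, two_cluster = sw$is_two_cluster,
               gc = gc_content(contigs[[id]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
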