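#' Viral read-profiling parameters
#'
#' Recruitment keeps hits with query coverage strictly over 0.65 and
#' E-value strictly under 1e-3; taxonomic assignment drops hits with bit
#' score below 30 before the lowest-common-ancestor step; cellular read
#' removal tolerates at most a 5% mismatch fraction on an end-to-end
#' placement.
#'
#' @param min_query_cov query-coverage floor (exclusive).
#' @param max_evalue E-value ceiling (exclusive).
#' @param min_lca_score bit-score floor for hits entering the LCA.
#' @param cellular_max_mismatch_frac mismatch fraction tolerated when
#'   matching reads to cellular references.
#' @param seed_k exact k-mer seed length for the cellular scan.
#' @return list of class `profiler_params`.
#' @export
profiler_params <- function(min_query_cov = 0.65, max_evalue = 1e-3,
                            min_lca_score = 30,
                            cellular_max_mismatch_frac = 0.05,
                            seed_k = 20L) {
  stopifnot(min_query_cov >= 0, min_query_cov <= 1, max_evalue >= 0,
            min_lca_score >= 0, cellular_max_mismatch_frac >= 0,
            cellular_max_mismatch_frac <= 1)
  structure(list(min_query_cov = min_query_cov, max_evalue = max_evalue,
                 min_lca_score = min_lca_score,
                 cellular_max_mismatch_frac = cellular_max_mismatch_frac,
                 seed_k = as.integer(seed_k)),
            class = "profiler_params")
}

#' Build a validated taxonomy tree
#'
#' @param nodes data.frame with columns `id`, `name`, `rank`, `parent`.
#'   The root is the single node whose parent equals its own id.
#' @return data.frame of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("id", "name", "rank", "parent") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  root <- nodes$id[nodes$id == nodes$parent]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  if (!all(nodes$parent %in% nodes$id))
    stop("every node's parent must exist in the taxonomy")
  # cycle check: every node must reach the root
  for (id in nodes$id) {
    seen <- character(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen) stop("taxonomy contains a cycle at node ", cur)
      seen <- c(seen, cur)
      cur <- nodes$parent[match(cur, nodes$id)]
    }
  }
  structure(nodes, class = c("taxonomy_tree", "data.frame"))
}

# path from a taxon up to the root, taxon first
tax_path <- function(tree, id) {
  id <- as.character(id)
  i <- match(id, tree$id)
  if (is.na(i)) stop("taxon not present in taxonomy: ", id)
  path <- id
  while (tree$parent[i] != tree$id[i]) {
    i <- match(tree$parent[i], tree$id)
    path <- c(path, tree$id[i])
  }
  path
}

#' Read a BLAST-tabular hit file
#'
#' Expects a TSV with columns `query`, `subject`, `taxon`, `pident`,
#' `length`, `evalue`, `bitscore`, `coverage` (query coverage as a
#' fraction).
#'
#' @param file path.
#' @return hit data.frame.
#' @export
read_hits_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("query", "subject", "taxon", "pident", "length", "evalue",
            "bitscore", "coverage")
  if (!all(need %in% names(x)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  x$taxon <- as.character(x$taxon)
  x
}

#' Filter recruitment hits by coverage and E-value
#'
#' Retains hits with query coverage > `min_query_cov` and E-value
#' < `max_evalue` (strict inequalities). Idempotent.
#'
#' @param hits hit data.frame (see [read_hits_tsv()]).
#' @param params a [profiler_params()].
#' @return the retained hits.
#' @export
filter_hits <- function(hits, params = profiler_params()) {
  keep <- hits$coverage > params$min_query_cov &
    hits$evalue < params$max_evalue
  out <- hits[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Lowest-common-ancestor assignment for one read
#'
#' Drops hits with bit score below the LCA floor; if none remain the read
#' is unassigned (`NA`). Otherwise returns the deepest taxon that is an
#' ancestor-or-self of every remaining hit's taxon.
#'
#' @param hits hits for a single read (pre-filtered by [filter_hits()]).
#' @param tree a [taxonomy_tree()].
#' @param params a [profiler_params()].
#' @return a taxon id, or `NA_character_` if unassigned.
#' @export
lca_assign <- function(hits, tree, params = profiler_params()) {
  hits <- hits[hits$bitscore >= params$min_lca_score, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_character_)
  paths <- lapply(unique(hits$taxon), function(t) rev(tax_path(tree, t)))
  # walk down from the root while all paths agree
  depth <- min(lengths(paths))
  lca <- paths[[1]][1]
  for (d in seq_len(depth)) {
    lev <- vapply(paths, `[`, "", d)
    if (length(unique(lev)) > 1L) break
    lca <- lev[1]
  }
  lca
}

#' Remove reads matching cellular reference sequences
#'
#' Discards any read that can be placed end-to-end on a reference (either
#' strand) with at most `cellular_max_mismatch_frac` of its positions
#' mismatching. Candidate placements are found by exact k-mer seeds taken
#' along the read, then verified by an ungapped substitution-only
#' comparison; reads without any seed hit are kept.
#'
#' @param reads read-set data.frame (`id`, `seq`, `qual`).
#' @param cellular_refs named character vector of reference sequences.
#' @param params a [profiler_params()].
#' @return the retained (putatively non-cellular) reads.
#' @export
remove_cellular <- function(reads, cellular_refs, params = profiler_params()) {
  stopifnot(length(cellular_refs) > 0)
  k <- params$seed_k
  is_cellular <- function(s) {
    L <- nchar(s)
    if (L < k) return(FALSE)
    max_mm <- floor(params$cellular_max_mismatch_frac * L)
    for (query in c(s, revcomp(s))) {
      qi <- utf8ToInt(query)
      seed_starts <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
      for (ref in cellular_refs) {
        rl <- nchar(ref)
        if (rl < L) next
        ri <- utf8ToInt(ref)
        for (ss in seed_starts) {
          seed <- substr(query, ss, ss + k - 1L)
          occ <- gregexpr(seed, ref, fixed = TRUE)[[1]]
          if (occ[1] == -1L) next
          for (o in occ) {
            off <- o - ss          # placement start - 1
            if (off < 0L || off + L > rl) next
            mm <- sum(qi != ri[(off + 1L):(off + L)])
            if (mm <= max_mm) return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  keep <- !vapply(reads$seq, is_cellular, logical(1), USE.NAMES = FALSE)
  out <- reads[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Relative-abundance profile at a taxonomic rank
#'
#' Rolls assignments up to the requested rank (reads assigned below the
#' rank are counted at their ancestor of that rank; reads assigned above
#' it are excluded from the rank's rows) and standardizes by the total
#' library size.
#'
#' @param assignments character vector of taxon ids (NA = unassigned).
#' @param tree a [taxonomy_tree()].
#' @param level rank name, e.g. `"family"` or `"order"`.
#' @param total_reads total reads in the library (>= assigned reads).
#' @return data.frame with `taxon`, `name`, `count`,
#'   `relative_abundance`.
#' @export
profile <- function(assignments, tree, level, total_reads) {
  if (!level %in% tree$rank)
    stop("unknown rank: ", level)
  assignments <- assignments[!is.na(assignments)]
  stopifnot(total_reads >= length(assignments))
  at_level <- vapply(assignments, function(a) {
    p <- tax_path(tree, a)
    hit <- p[tree$rank[match(p, tree$id)] == level]
    if (length(hit)) hit[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  at_level <- at_level[!is.na(at_level)]
  if (!length(at_level))
    return(data.frame(taxon = character(0), name = character(0),
                      count = integer(0), relative_abundance = numeric(0)))
  tab <- table(at_level)
  data.frame(taxon = names(tab),
             name = tree$name[match(names(tab), tree$id)],
             count = as.integer(tab),
             relative_abundance = as.numeric(tab) / total_reads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Roll species-level viral assignments up to host phyla
#'
#' Species-level assignments are mapped to the phylum of their putative
#' host through the supplied virus-to-host map; assignments at higher
#' ranks are tallied as `host-unresolved`.
#'
#' @param assignments character vector of taxon ids (NA = unassigned,
#'   skipped).
#' @param tree a [taxonomy_tree()].
#' @param host_map data.frame with columns `taxon` (viral species id) and
#'   `host_phylum`.
#' @return data.frame with `host_phylum` and `count`.
#' @export
host_rollup <- function(assignments, tree, host_map) {
  assignments <- assignments[!is.na(assignments)]
  rank <- tree$rank[match(assignments, tree$id)]
  lab <- ifelse(rank == "species",
                host_map$host_phylum[match(assignments, host_map$taxon)],
                "host-unresolved")
  lab[is.na(lab)] <- "host-unresolved"
  tab <- table(lab)
  data.frame(host_phylum = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
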