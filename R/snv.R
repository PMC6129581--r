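#' SNV caller parameters
#'
#' A deliberately transparent quality-aware binomial caller: at each site
#' of sufficient depth the top non-reference allele count is tested
#' against the pooled sequencing-error rate derived from base qualities,
#' with Bonferroni control over the tested sites.
#'
#' @param min_base_quality Phred floor for bases entering the pileup.
#' @param min_depth minimum depth for a site to be tested.
#' @param alpha family-wise significance level (Bonferroni-corrected over
#'   tested sites).
#' @return list of class `snv_params`.
#' @export
snv_params <- function(min_base_quality = 20L, min_depth = 10L,
                       alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, min_depth >= 1L)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_depth = as.integer(min_depth), alpha = alpha),
            class = "snv_params")
}

#' Build a per-site pileup from ungapped alignments
#'
#' Tallies A/C/G/T counts per genome position from single-segment
#' ungapped alignment records, keeping only bases at or above the quality
#' floor. Minus-strand records are reverse-complemented into plus-strand
#' orientation first. The mean per-base error probability of the counted
#' bases is recorded per site for the caller's error model.
#'
#' @param alignments data.frame with columns `pos` (1-based leftmost),
#'   `strand`, `seq`, `qual` (as read from [read_sam_ungapped()] or the
#'   simulator manifest joined to its reads).
#' @param genome genome string (named character vector of length 1).
#' @param min_base_quality Phred floor.
#' @return data.frame of class `pileup`: `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `depth`, `mean_err` for every covered position.
#' @export
build_pileup <- function(alignments, genome, min_base_quality = 20L) {
  gseq <- toupper(unname(genome)[1])
  L <- nchar(gseq)
  n <- nrow(alignments)
  seqs <- alignments$seq
  quals <- alignments$qual
  neg <- alignments$strand == "-"
  if (any(neg)) {
    seqs[neg] <- revcomp(seqs[neg])
    quals[neg] <- vapply(quals[neg], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  lens <- nchar(seqs)
  if (any(alignments$pos < 1L) || any(alignments$pos + lens - 1L > L))
    stop("alignment extends beyond the genome end")
  pos <- unlist(lapply(seq_len(n),
                       function(i) alignments$pos[i]:(alignments$pos[i] +
                                                        lens[i] - 1L)))
  base <- unlist(strsplit(toupper(seqs), "", fixed = TRUE))
  q <- unlist(lapply(quals, phred_to_int))
  ok <- q >= min_base_quality & base %in% DNA_BASES
  pos <- pos[ok]; base <- base[ok]; q <- q[ok]
  if (!length(pos))
    return(structure(data.frame(pos = integer(0), ref = character(0),
                                A = integer(0), C = integer(0),
                                G = integer(0), T = integer(0),
                                depth = integer(0), mean_err = numeric(0)),
                     class = c("pileup", "data.frame")))
  upos <- sort(unique(pos))
  pf <- factor(pos, levels = upos)
  counts <- vapply(DNA_BASES, function(b)
    as.integer(tabulate(pf[base == b], nbins = length(upos))),
    integer(length(upos)))
  if (length(upos) == 1L) counts <- matrix(counts, nrow = 1L,
                                           dimnames = list(NULL, DNA_BASES))
  err_sum <- vapply(split(phred_error_prob(q), pf), sum, numeric(1))
  depth <- as.integer(rowSums(counts))
  out <- data.frame(pos = upos,
                    ref = substring(gseq, upos, upos),
                    counts, depth = depth,
                    mean_err = as.numeric(err_sum) / depth,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("pileup", "data.frame"))
}

#' Call single-nucleotide variants from a pileup
#'
#' At each site with depth >= `min_depth`, the pooled error rate is the
#' mean per-base error probability of the counted bases; the top
#' non-reference allele with count k of n is tested against the upper
#' binomial tail P(X >= k | n, err/3) and emitted when the p-value passes
#' the Bonferroni-corrected level `alpha / n_tested_sites`. The reported
#' frequency is k/n.
#'
#' @param pileup a [build_pileup()] result.
#' @param params a [snv_params()].
#' @param contig contig id recorded in the calls.
#' @return data.frame of SNVs: `contig`, `position`, `ref`, `alt`,
#'   `frequency`, `depth`, `p_value`.
#' @export
call_snvs <- function(pileup, params = snv_params(), contig = "genome") {
  tested <- pileup[pileup$depth >= params$min_depth &
                     pileup$ref %in% DNA_BASES, , drop = FALSE]
  m <- nrow(tested)
  empty <- data.frame(contig = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      frequency = numeric(0), depth = integer(0),
                      p_value = numeric(0))
  if (m == 0L) return(empty)
  cn <- as.matrix(tested[, DNA_BASES])
  ref_idx <- match(tested$ref, DNA_BASES)
  cn_alt <- cn
  cn_alt[cbind(seq_len(m), ref_idx)] <- -1L   # mask the reference allele
  alt_idx <- max.col(cn_alt, ties.method = "first")
  k <- cn_alt[cbind(seq_len(m), alt_idx)]
  n <- tested$depth
  p <- pbinom(k - 1L, n, tested$mean_err / 3, lower.tail = FALSE)
  emit <- k > 0L & p <= params$alpha / m
  if (!any(emit)) return(empty)
  data.frame(contig = contig, position = tested$pos[emit],
             ref = tested$ref[emit], alt = DNA_BASES[alt_idx[emit]],
             frequency = k[emit] / n[emit], depth = n[emit],
             p_value = p[emit], row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-ORF SNV density
#'
#' @param snvs SNV data.frame (column `position`).
#' @param orfs ORF data.frame (columns `orf_id`, `start`, `end`).
#' @return data.frame: `orf_id`, `length`, `n_snvs`, `snvs_per_100bp`.
#' @export
snv_density_per_orf <- function(snvs, orfs) {
  n <- vapply(seq_len(nrow(orfs)), function(i)
    sum(snvs$position >= orfs$start[i] & snvs$position <= orfs$end[i]),
    integer(1))
  len <- orfs$end - orfs$start + 1L
  data.frame(orf_id = orfs$orf_id, length = len, n_snvs = n,
             snvs_per_100bp = 100 * n / len, stringsAsFactors = FALSE)
}

# genome positions (plus strand) covered by codon index ci of an ORF
codon_span <- function(orf, ci) {
  if (orf$strand == "+") (orf$start + 3L * ci) + 0:2
  else (orf$end - 3L * ci) - 0:2
}

#' Classify the coding effect of an SNV
#'
#' An SNV outside every ORF is noncoding. Otherwise the containing codon
#' is read in coding orientation (reverse-complemented for minus-strand
#' ORFs), the alternate codon is formed by the single substitution, and
#' the effect follows the standard genetic code.
#'
#' @param genome genome string (named character vector of length 1).
#' @param orfs ORF data.frame (columns `start`, `end`, `strand`); lengths
#'   must be divisible by 3.
#' @param snv one SNV (list/row with `position`, `ref`, `alt`).
#' @return list with `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` in {"synonymous", "nonsynonymous", "noncoding"}.
#' @export
codon_effect <- function(genome, orfs, snv) {
  gseq <- toupper(unname(genome)[1])
  pos <- snv$position
  hit <- which(orfs$start <= pos & orfs$end >= pos)
  if (!length(hit))
    return(list(ref_codon = NA_character_, alt_codon = NA_character_,
                ref_aa = NA_character_, alt_aa = NA_character_,
                effect = "noncoding"))
  orf <- orfs[hit[1], , drop = FALSE]
  if ((orf$end - orf$start + 1L) %% 3L != 0L)
    stop("ORF length not divisible by 3: ", orf$orf_id %||% "")
  ci <- if (orf$strand == "+") (pos - orf$start) %/% 3L
        else (orf$end - pos) %/% 3L
  span <- codon_span(orf, ci)          # plus-strand positions, coding order
  plus_codon <- paste(substring(gseq, sort(span), sort(span)), collapse = "")
  ref_codon <- if (orf$strand == "+") plus_codon else revcomp(plus_codon)
  cp <- which(span == pos)             # position within the coding codon
  alt_base <- if (orf$strand == "+") toupper(snv$alt)
              else chartr("ACGT", "TGCA", toupper(snv$alt))
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  list(ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa,
       effect = if (identical(ref_aa, alt_aa)) "synonymous"
                else "nonsynonymous")
}

#' Which allele does the spacer carry at an SNV site?
#'
#' Reads the spacer base aligned to the SNV position (complemented for
#' minus-strand proto-spacer hits), reports which population allele it
#' equals and that allele's frequency (alt frequency, or 1 - alt
#' frequency for the reference allele).
#'
#' @param spacer the spacer sequence.
#' @param hit one proto-spacer hit (list/row with `start`, `end`,
#'   `strand`).
#' @param snv one SNV (list/row with `position`, `ref`, `alt`,
#'   `frequency`).
#' @return list with `allele` in {"ref", "alt", "neither"} and
#'   `frequency` (NA for "neither").
#' @export
spacer_allele_concordance <- function(spacer, hit, snv) {
  pos <- snv$position
  if (pos < hit$start || pos > hit$end)
    stop("SNV position outside the proto-spacer interval")
  sbase <- if (hit$strand == "+")
    substr(spacer, pos - hit$start + 1L, pos - hit$start + 1L)
  else
    chartr("ACGT", "TGCA",
           substr(spacer, hit$end - pos + 1L, hit$end - pos + 1L))
  sbase <- toupper(sbase)
  if (sbase == toupper(snv$alt))
    list(allele = "alt", frequency = snv$frequency)
  else if (sbase == toupper(snv$ref))
    list(allele = "ref", frequency = 1 - snv$frequency)
  else
    list(allele = "neither", frequency = NA_real_)
}

# effect label in the report's notation: "Silent", "refaa/altaa", or en
# dash for noncoding sites
effect_label <- function(ce) {
  switch(ce$effect,
         synonymous = "Silent",
         nonsynonymous = paste0(ce$ref_aa, "/", ce$alt_aa),
         "–")
}

EMPTY_CELL <- "–"   # en dash, as printed in the reference table

#' Assemble the virotope report
#'
#' Joins every (spacer, proto-spacer hit) pair with the SNVs falling
#' inside the proto-spacer: mismatch positions, alleles, the frequency of
#' the spacer-carried allele, coding effects and codon changes. One row
#' per pair, ordered by locus then proto-spacer start; empty cells are
#' the en dash, matching the packaged reference table's conventions.
#'
#' @param spacers named character vector of spacer sequences (names =
#'   spacer ids).
#' @param hits proto-spacer hits from [match_spacers()].
#' @param snvs SNV data.frame from [call_snvs()].
#' @param orfs ORF data.frame (for viral-target labels and codon
#'   effects).
#' @param genome genome string.
#' @param spacer_info optional data.frame (`spacer_id`, `locus`,
#'   `temperature`) carrying locus/temperature labels; defaults derive
#'   the locus from the spacer id prefix.
#' @return data.frame with the same columns as [load_virotope_table()].
#' @export
make_virotope_report <- function(spacers, hits, snvs, orfs, genome,
                                 spacer_info = NULL) {
  if (nrow(hits) == 0L)
    return(load_virotope_table()[0, ])
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    sp <- spacers[[h$spacer_id]]
    info <- if (!is.null(spacer_info) && h$spacer_id %in%
                  spacer_info$spacer_id)
      spacer_info[match(h$spacer_id, spacer_info$spacer_id), , drop = FALSE]
    else data.frame(locus = sub("_spacer[0-9]+$", "", h$spacer_id),
                    temperature = NA_character_)
    ov <- orfs[orfs$start <= h$end & orfs$end >= h$start, , drop = FALSE]
    target <- if (nrow(ov)) ov$product[which.max(
      pmin(ov$end, h$end) - pmax(ov$start, h$start))] else "NC"
    s <- snvs[snvs$position >= h$start & snvs$position <= h$end, ,
              drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    if (nrow(s)) {
      conc <- lapply(seq_len(nrow(s)), function(j)
        spacer_allele_concordance(sp, h, s[j, ]))
      ce <- lapply(seq_len(nrow(s)), function(j)
        codon_effect(genome, orfs, s[j, ]))
      snv_pos <- paste(s$position, collapse = "; ")
      alleles <- paste(paste0(s$ref, "/", s$alt), collapse = "; ")
      freqs <- paste(vapply(conc, function(x)
        if (is.na(x$frequency)) EMPTY_CELL else
          format(round(x$frequency, 3)), character(1)), collapse = "; ")
      labels <- vapply(ce, effect_label, character(1))
      eff <- if (all(labels == EMPTY_CELL)) EMPTY_CELL
             else if (length(labels) > 1L && all(labels == "Silent"))
               "All silent"
             else paste(labels, collapse = "; ")
      codons <- vapply(ce, function(x)
        if (is.na(x$ref_codon)) EMPTY_CELL
        else paste0(x$ref_codon, "/", x$alt_codon), character(1))
      codon_cell <- if (all(codons == EMPTY_CELL)) EMPTY_CELL
                    else paste(codons, collapse = "; ")
    } else {
      snv_pos <- alleles <- freqs <- eff <- codon_cell <- EMPTY_CELL
    }
    mmp <- h$mismatch_positions
    data.frame(temperature = as.character(info$temperature),
               spacer = sp, viral_target = target, locus = info$locus,
               protospacer_start = h$start, protospacer_end = h$end,
               mismatch_positions = if (nzchar(mmp))
                 gsub(";", "; ", mmp, fixed = TRUE) else EMPTY_CELL,
               snv_positions = snv_pos, alleles = alleles,
               crispr_allele_freq = freqs, snv_effect = eff,
               codon_change = codon_cell, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$locus, out$protospacer_start), , drop = FALSE]
}

# split a multi-entry cell; empty cells give character(0)
split_cell <- function(x) {
  if (is.na(x) || x == EMPTY_CELL || x == "" || x == "-") return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Summarize a virotope report
#'
#' Counts rows, distinct loci, SNV-bearing and mismatch-bearing rows, and
#' SNV entries by coding effect. Entries are counted per (row, listed
#' position), so a genomic site reported at two temperatures counts
#' twice. Effect cells follow the report notation: "Silent" / "All
#' silent" (synonymous), "X/Y" amino-acid pairs (nonsynonymous), en dash
#' (noncoding).
#'
#' @param rows a virotope report ([make_virotope_report()] or
#'   [load_virotope_table()]).
#' @return list of class `virotope_summary` with `n_rows`,
#'   `n_distinct_loci`, `n_rows_with_snv`, `n_rows_with_mismatch`,
#'   `n_snv_entries`, `n_synonymous`, `n_nonsynonymous`, `n_noncoding`.
#' @export
summarize_virotopes <- function(rows) {
  entries <- lapply(rows$snv_positions, split_cell)
  n_entries <- lengths(entries)
  syn <- nonsyn <- noncod <- 0L
  for (i in seq_len(nrow(rows))) {
    ne <- n_entries[i]
    if (ne == 0L) next
    cell <- rows$snv_effect[i]
    if (is.na(cell) || cell == EMPTY_CELL || cell == "") {
      noncod <- noncod + ne
    } else if (cell == "All silent") {
      syn <- syn + ne
    } else {
      items <- split_cell(cell)
      if (length(items) == 1L && ne > 1L) items <- rep(items, ne)
      for (it in items) {
        if (it == "Silent") syn <- syn + 1L
        else if (it == EMPTY_CELL || it == "-") noncod <- noncod + 1L
        else nonsyn <- nonsyn + 1L
      }
    }
  }
  structure(list(
    n_rows = nrow(rows),
    n_distinct_loci = length(unique(rows$locus)),
    n_rows_with_snv = sum(n_entries > 0L),
    n_rows_with_mismatch = sum(vapply(rows$mismatch_positions,
                                      function(x) length(split_cell(x)) > 0L,
                                      logical(1))),
    n_snv_entries = sum(n_entries),
    n_synonymous = syn, n_nonsynonymous = nonsyn, n_noncoding = noncod),
    class = "virotope_summary")
}

#' @export
print.virotope_summary <- function(x, ...) {
  cat("Virotope report summary\n")
  cat(sprintf("  rows: %d (distinct loci: %d)\n", x$n_rows,
              x$n_distinct_loci))
  cat(sprintf("  rows with SNVs: %d; rows with spacer mismatches: %d\n",
              x$n_rows_with_snv, x$n_rows_with_mismatch))
  cat(sprintf("  SNV entries: %d (%d synonymous, %d nonsynonymous, %d noncoding)\n",
              x$n_snv_entries, x$n_synonymous, x$n_nonsynonymous,
              x$n_noncoding))
  invisible(x)
}

#' Write SNV calls as a VCF-like TSV
#'
#' @param snvs SNV data.frame from [call_snvs()].
#' @param file path.
#' @return the path, invisibly.
#' @export
write_snv_tsv <- function(snvs, file) {
  out <- data.frame(CHROM = snvs$contig, POS = snvs$position,
                    REF = snvs$ref, ALT = snvs$alt, AF = snvs$frequency,
                    DP = snvs$depth, P = snvs$p_value)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
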