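#' Configuration for the synthetic mat community
#'
#' Bundles every knob of the synthetic-community generator. Defaults
#' emulate the study system: a ~40.7 kb circular T7-like cyanopodovirus
#' genome at 43.9% GC with 39 ORFs laid out in two transcriptional
#' clusters, and a cyanobacterial host contig carrying CRISPR
#' repeat-spacer arrays whose spacers target the phage.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param phage_length phage genome length in bp (>= 1000).
#' @param gc_target target GC fraction in \[0, 1\].
#' @param n_orfs number of ORFs on the phage genome.
#' @param pivot_orfs number of leading (sense-strand) ORFs; all ORFs after
#'   the pivot are antisense. Default splits roughly replication/structural
#'   as in T7-like genomes.
#' @param n_crispr_loci number of CRISPR arrays on the host contig.
#' @param spacers_per_locus spacers per array (repeats = spacers + 1).
#' @param planted_mismatches_per_spacer substitutions planted in each
#'   phage-derived spacer, 0..3.
#' @param spacer_length spacer length in bp (25..60).
#' @param repeat_length CRISPR repeat length in bp (23..55).
#' @param phage_spacer_fraction fraction of spacers sampled from the phage
#'   (the rest are random, emulating targets lost to databases).
#' @param host_length host contig length in bp.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param dna_depth,rna_depth mean fold-coverage for the DNA and RNA
#'   channels.
#' @param planted_snvs data.frame with columns `position`, `alt`,
#'   `fraction` (and optionally `contig`): intra-population variants
#'   planted into phage reads at the given allele fractions.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       phage_length = 40740L,
                       gc_target = 0.439,
                       n_orfs = 39L,
                       pivot_orfs = ceiling(0.36 * n_orfs),
                       n_crispr_loci = 1L,
                       spacers_per_locus = 3L,
                       planted_mismatches_per_spacer = 0L,
                       spacer_length = 36L,
                       repeat_length = 36L,
                       phage_spacer_fraction = 1,
                       host_length = 20000L,
                       read_length = 100L,
                       error_rate = 0.001,
                       dna_depth = 50,
                       rna_depth = 10,
                       planted_snvs = NULL) {
  cfg <- list(seed = as.integer(seed), phage_length = as.integer(phage_length),
              gc_target = gc_target, n_orfs = as.integer(n_orfs),
              pivot_orfs = as.integer(pivot_orfs),
              n_crispr_loci = as.integer(n_crispr_loci),
              spacers_per_locus = as.integer(spacers_per_locus),
              planted_mismatches_per_spacer =
                as.integer(planted_mismatches_per_spacer),
              spacer_length = as.integer(spacer_length),
              repeat_length = as.integer(repeat_length),
              phage_spacer_fraction = phage_spacer_fraction,
              host_length = as.integer(host_length),
              read_length = as.integer(read_length),
              error_rate = error_rate, dna_depth = dna_depth,
              rna_depth = rna_depth, planted_snvs = planted_snvs)
  stopifnot(cfg$phage_length >= 1000L,
            cfg$gc_target >= 0, cfg$gc_target <= 1,
            cfg$planted_mismatches_per_spacer >= 0L,
            cfg$planted_mismatches_per_spacer <= 3L,
            cfg$spacer_length >= 25L, cfg$spacer_length <= 60L,
            cfg$repeat_length >= 23L, cfg$repeat_length <= 55L,
            cfg$error_rate >= 0, cfg$error_rate < 1)
  if (!is.null(planted_snvs)) {
    stopifnot(is.data.frame(planted_snvs),
              all(c("position", "alt", "fraction") %in% names(planted_snvs)),
              all(planted_snvs$position >= 1),
              all(planted_snvs$position <= cfg$phage_length),
              all(planted_snvs$fraction > 0), all(planted_snvs$fraction < 1))
  }
  structure(cfg, class = "sim_config")
}

# random DNA with exact composition: a uniform permutation of a fixed base
# multiset matching gc; realized GC is round(n*gc)/n for every draw.
random_dna <- function(n, gc) {
  n_gc <- round(n * gc)
  n_g <- n_gc %/% 2L
  n_a <- (n - n_gc) %/% 2L
  bases <- c(rep("G", n_g), rep("C", n_gc - n_g),
             rep("A", n_a), rep("T", n - n_gc - n_a))
  paste(sample(bases), collapse = "")
}

# product labels for the two clusters, cycled over the cluster sizes.
# Sense cluster: DNA replication/modification; antisense: virion assembly.
SENSE_PRODUCTS <- c("DNA polymerase", "hypothetical protein",
                    "DNA primase/helicase", "hypothetical protein",
                    "dTMP kinase", "hypothetical protein")
ANTISENSE_PRODUCTS <- c("terminase", "portal protein", "scaffold protein",
                        "major capsid protein", "tail tubular protein A",
                        "tail tubular protein B",
                        "internal protein-M23-peptidase", "tail protein",
                        "tail fiber protein",
                        "deoxycytidine triphosphate deaminase",
                        "hypothetical protein")

#' Generate a synthetic phage genome with a two-cluster ORF layout
#'
#' Draws a genome of exactly `phage_length` bp whose base composition
#' matches `gc_target`, and lays out `n_orfs` non-overlapping ORFs (lengths
#' divisible by 3): all ORFs up to the pivot are on the sense strand, all
#' after it on the antisense strand, mirroring the replication-module /
#' virion-assembly split of T7-like cyanopodoviruses.
#'
#' @param config a [sim_config()].
#' @param circular if `TRUE`, the first `overhang` bases are duplicated at
#'   the 3' end, as an assembler emits a circular contig.
#' @param overhang terminal duplication length for circular output.
#' @return list with `genome` (named character vector of length 1) and
#'   `orfs` (data.frame: contig, orf_id, start, end, strand, product,
#'   class).
#' @export
make_phage_genome <- function(config = sim_config(), circular = FALSE,
                              overhang = 30L) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$phage_length
  n <- config$n_orfs
  min_orf <- 90L; min_gap <- 10L
  if (n * (min_orf + min_gap) > L)
    stop(sprintf(paste0("n_orfs incompatible with phage_length: %d ORFs need ",
                        "at least %d bp (>= %d bp ORF + %d bp gap each) but ",
                        "the genome is %d bp"),
                 n, n * (min_orf + min_gap), min_orf, min_gap, L))
  set.seed(config$seed)
  seq <- random_dna(L, config$gc_target)

  # partition the genome into n [gap, orf] blocks; ~95% coding
  gaps <- pmax(min_gap, round(runif(n, 0.5, 1.5) * (0.05 * L / n)))
  w <- runif(n, 0.5, 1.5)
  coding <- L - sum(gaps)
  lens <- pmax(min_orf, 3L * floor(w * coding / sum(w) / 3))
  # shrink uniformly if rounding overshot
  while (sum(lens) + sum(gaps) > L) lens[which.max(lens)] <-
    lens[which.max(lens)] - 3L
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    pos <- ends[i] + 1L
  }
  strand <- ifelse(seq_len(n) <= config$pivot_orfs, "+", "-")
  n_sense <- sum(strand == "+")
  product <- c(rep_len(SENSE_PRODUCTS, n_sense),
               rep_len(ANTISENSE_PRODUCTS, n - n_sense))
  class <- ifelse(product == "hypothetical protein", "hypothetical", "core")
  orfs <- data.frame(contig = "synthetic_phage",
                     orf_id = sprintf("CDS%02d", seq_len(n)),
                     start = starts, end = ends, strand = strand,
                     product = product, class = class,
                     stringsAsFactors = FALSE)
  if (circular) seq <- paste0(seq, substr(seq, 1L, overhang))
  list(genome = c(synthetic_phage = seq), orfs = orfs)
}

#' Generate a host contig carrying CRISPR arrays targeting a phage
#'
#' Embeds `n_crispr_loci` repeat-spacer arrays in a random host contig.
#' A configurable fraction of spacers are substrings of the phage (either
#' strand) with exactly `planted_mismatches_per_spacer` substitutions
#' planted at interior spacer positions (never at the termini). The
#' returned truth records each locus (repeat consensus and coordinates,
#' ordered spacers) and each planted proto-spacer placement (plus-strand
#' interval, strand, plus-strand mismatch positions).
#'
#' @param config a [sim_config()].
#' @param phage named character vector of length 1: the phage genome.
#' @return list with `host` (named character vector), `loci` (list of
#'   locus truth records) and `placements` (data.frame: spacer_id, start,
#'   end, strand, mismatch_positions as ";"-joined string, planted flag).
#' @export
make_host_with_crispr <- function(config, phage) {
  stopifnot(inherits(config, "sim_config"),
            is.character(phage), length(phage) == 1L)
  pseq <- unname(phage)
  pname <- names(phage)
  sl <- config$spacer_length
  rl <- config$repeat_length
  if (sl > nchar(pseq))
    stop("requested spacer length exceeds the phage genome length")
  set.seed(config$seed + 1L)
  nl <- config$n_crispr_loci
  nsp <- config$spacers_per_locus
  nmm <- config$planted_mismatches_per_spacer

  # one array: repeats (nsp + 1) interleaved with nsp spacers
  arrays <- vector("list", nl)
  placements <- list()
  for (li in seq_len(nl)) {
    rep_seq <- random_dna(rl, 0.42)
    spacers <- character(nsp)
    for (si in seq_len(nsp)) {
      sid <- sprintf("locus%d_spacer%d", li, si)
      if (runif(1) <= config$phage_spacer_fraction) {
        gstart <- sample.int(nchar(pseq) - sl + 1L, 1L)
        gend <- gstart + sl - 1L
        strand <- if (runif(1) < 0.5) "+" else "-"
        sp <- substr(pseq, gstart, gend)
        if (strand == "-") sp <- revcomp(sp)
        mm_genome <- integer(0)
        if (nmm > 0L) {
          # interior spacer positions, never termini
          mm_sp <- sort(sample(2:(sl - 1L), nmm))
          ch <- seq_chars(sp)
          for (j in mm_sp) ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1L)
          sp <- paste(ch, collapse = "")
          mm_genome <- if (strand == "+") gstart + mm_sp - 1L
                       else gend - mm_sp + 1L
        }
        placements[[length(placements) + 1L]] <- data.frame(
          spacer_id = sid, target = pname, start = gstart, end = gend,
          strand = strand,
          mismatch_positions = paste(sort(mm_genome), collapse = ";"),
          planted = TRUE, stringsAsFactors = FALSE)
      } else {
        sp <- random_dna(sl, 0.45)
      }
      spacers[si] <- sp
    }
    arrays[[li]] <- list(id = sprintf("locus%d", li), repeat_seq = rep_seq,
                         spacers = spacers)
  }

  # splice arrays into background at evenly spaced offsets
  arr_str <- vapply(arrays, function(a) {
    paste0(paste0(a$repeat_seq, a$spacers, collapse = ""), a$repeat_seq)
  }, character(1))
  arr_len <- nchar(arr_str)
  bg_total <- config$host_length - sum(arr_len)
  if (bg_total < nl + 1L)
    stop("host_length too small for the requested CRISPR arrays")
  bg_len <- as.integer(diff(floor(seq(0, bg_total, length.out = nl + 2L))))
  pieces <- character(0)
  loci <- vector("list", nl)
  pos <- 1L
  for (li in seq_len(nl)) {
    pieces <- c(pieces, random_dna(bg_len[li], 0.42))
    pos <- pos + bg_len[li]
    a <- arrays[[li]]
    nrep <- nsp + 1L
    rep_starts <- pos + (0:(nrep - 1L)) * (rl + sl)
    sp_starts <- rep_starts[-nrep] + rl
    loci[[li]] <- list(
      locus_id = a$id, contig = "synthetic_host",
      repeat_consensus = a$repeat_seq,
      repeat_intervals = data.frame(start = rep_starts,
                                    end = rep_starts + rl - 1L),
      spacers = data.frame(id = sprintf("%s_spacer%d", a$id, seq_len(nsp)),
                           seq = a$spacers, start = sp_starts,
                           end = sp_starts + sl - 1L,
                           stringsAsFactors = FALSE))
    pieces <- c(pieces, arr_str[li])
    pos <- pos + arr_len[li]
  }
  pieces <- c(pieces, random_dna(bg_len[nl + 1L], 0.42))
  host <- paste(pieces, collapse = "")
  placements <- if (length(placements)) do.call(rbind, placements)
                else data.frame(spacer_id = character(0), target = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0),
                                mismatch_positions = character(0),
                                planted = logical(0))
  list(host = c(synthetic_host = host), loci = loci, placements = placements)
}

#' Simulate a shotgun read set with planted variants
#'
#' Draws uniformly positioned single-end reads from each genome at the
#' requested mean fold-coverage, plants intra-population SNVs into
#' phage-derived reads at their true allele fractions (per-read Bernoulli
#' draws), then applies substitution errors at `error_rate` with constant
#' per-read Phred qualities consistent with the error model
#' (Q = -10 log10(error_rate)). Reads are drawn from both strands.
#'
#' @param genomes named character vector of genome sequences.
#' @param depths named numeric vector of mean fold-coverage per genome
#'   (names must match `genomes`); a depth of 0 yields no reads.
#' @param channel `"DNA"` or `"RNA"`; recorded in read ids and the
#'   manifest.
#' @param config a [sim_config()].
#' @return list with `reads` (data.frame id/seq/qual, FASTQ-ready),
#'   `manifest` (truth: one row per read with source genome, position and
#'   strand) and `snv_truth` (realized per-site planted allele fractions).
#' @export
make_reads <- function(genomes, depths, channel = c("DNA", "RNA"),
                       config = sim_config()) {
  channel <- match.arg(channel)
  stopifnot(is.character(genomes), !is.null(names(genomes)),
            all(names(depths) %in% names(genomes)),
            all(depths >= 0), any(depths > 0))
  rl <- config$read_length
  if (rl > min(nchar(genomes[names(depths)[depths > 0]])))
    stop("read_length exceeds the shortest genome with positive depth")
  set.seed(config$seed + if (channel == "DNA") 2L else 3L)
  er <- config$error_rate
  q <- if (er > 0) as.integer(round(-10 * log10(er))) else 40L
  qual1 <- int_to_phred(rep(q, rl))

  snvs <- config$planted_snvs
  if (!is.null(snvs)) {
    if (is.null(snvs$contig)) snvs$contig <- names(genomes)[1]
    for (k in seq_len(nrow(snvs))) {
      g <- snvs$contig[k]
      if (g %in% names(genomes) &&
          substr(genomes[[g]], snvs$position[k], snvs$position[k]) ==
            snvs$alt[k])
        stop("planted alt allele equals the reference base at position ",
             snvs$position[k])
    }
  }

  all_reads <- list(); all_manifest <- list()
  snv_cover <- snv_alt <- if (is.null(snvs)) NULL else integer(nrow(snvs))
  for (g in names(depths)) {
    gl <- nchar(genomes[[g]])
    n <- round(depths[[g]] * gl / rl)
    if (n == 0) next
    starts <- sample.int(gl - rl + 1L, n, replace = TRUE)
    strands <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- substring(genomes[[g]], starts, starts + rl - 1L)
    # plant SNVs on the plus-strand window before errors/strand flip
    if (!is.null(snvs)) {
      gsn <- which(snvs$contig == g)
      for (k in gsn) {
        p <- snvs$position[k]
        cov <- which(starts <= p & starts + rl - 1L >= p)
        snv_cover[k] <- snv_cover[k] + length(cov)
        if (!length(cov)) next
        take <- cov[runif(length(cov)) < snvs$fraction[k]]
        snv_alt[k] <- snv_alt[k] + length(take)
        for (i in take)
          substr(seqs[i], p - starts[i] + 1L, p - starts[i] + 1L) <-
            snvs$alt[k]
      }
    }
    # substitution errors
    if (er > 0) {
      n_err <- rbinom(1L, n * rl, er)
      if (n_err > 0) {
        at <- sample.int(n * rl, n_err)
        ri <- (at - 1L) %/% rl + 1L
        bi <- (at - 1L) %% rl + 1L
        for (e in seq_len(n_err)) {
          old <- substr(seqs[ri[e]], bi[e], bi[e])
          substr(seqs[ri[e]], bi[e], bi[e]) <-
            sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }
    out_seq <- ifelse(strands == "-", revcomp(seqs), seqs)
    ids <- sprintf("%s_%s_read%06d", channel, g, seq_len(n))
    all_reads[[g]] <- data.frame(id = ids, seq = out_seq, qual = qual1,
                                 stringsAsFactors = FALSE)
    all_manifest[[g]] <- data.frame(qname = ids, rname = g, pos = starts,
                                    strand = strands, channel = channel,
                                    stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, c(all_reads, list(make.row.names = FALSE)))
  manifest <- do.call(rbind, c(all_manifest, list(make.row.names = FALSE)))
  snv_truth <- NULL
  if (!is.null(snvs)) {
    snv_truth <- cbind(snvs,
                       covering_reads = snv_cover, alt_reads = snv_alt,
                       realized_fraction = ifelse(snv_cover > 0,
                                                  snv_alt / snv_cover, NA))
  }
  list(reads = reads, manifest = manifest, snv_truth = snv_truth)
}

#' Write and read a truth manifest
#'
#' Serializes the per-read truth table (and optional planted-SNV truth) to
#' TSV so that a generated community round-trips through files.
#'
#' @param manifest data.frame as returned in `make_reads()$manifest`.
#' @param file path to a TSV file.
#' @return `read_truth_manifest` returns the manifest data.frame.
#' @export
write_truth_manifest <- function(manifest, file) {
  write.table(manifest, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Load the packaged CRISPR virotope reference table
#'
#' Returns the 25-row reference table of spacer/proto-spacer records
#' shipped with the package (one row per virotope: temperature, spacer
#' sequence, viral target, CRISPR locus, proto-spacer coordinates,
#' mismatch positions, SNVs with alleles and in-CRISPR allele frequencies,
#' coding effect and codon change). Cells are kept verbatim as printed in
#' the source table; the en dash "–" encodes an empty cell.
#'
#' @return data.frame with 25 rows and columns `temperature`, `spacer`,
#'   `viral_target`, `locus`, `protospacer_start`, `protospacer_end`,
#'   `mismatch_positions`, `snv_positions`, `alleles`,
#'   `crispr_allele_freq`, `snv_effect`, `codon_change`.
#' @export
load_virotope_table <- function() {
  path <- system.file("extdata", "crispr_virotopes_table.tsv",
                      package = "virotope", mustWork = TRUE)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", fileEncoding = "UTF-8")
  names(x) <- c("temperature", "spacer", "viral_target", "locus",
                "protospacer_start", "protospacer_end",
                "mismatch_positions", "snv_positions", "alleles",
                "crispr_allele_freq", "snv_effect", "codon_change")
  x$protospacer_start <- as.integer(x$protospacer_start)
  x$protospacer_end <- as.integer(x$protospacer_end)
  x
}
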