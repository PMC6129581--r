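# Independent oracles and small construction helpers shared across tests.
# These deliberately use different code paths from the package internals
# (per-offset loops over character vectors, direct formula evaluation).

# i.i.d. random DNA, independent of the package's composition sampler
rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rc_oracle <- function(s) {
  m <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(m[chars(s)]), collapse = "")
}

# brute-force spacer placement: every offset x both strands, Hamming
# distance by elementwise character comparison
oracle_match <- function(spacer, genome, cap) {
  g <- chars(genome)
  L <- length(g)
  m <- nchar(spacer)
  out <- list()
  for (strand in c("+", "-")) {
    q <- chars(if (strand == "+") spacer else rc_oracle(spacer))
    for (o in seq_len(L - m + 1L)) {
      win <- g[o:(o + m - 1L)]
      mm <- which(win != q)
      if (length(mm) <= cap)
        out[[length(out) + 1L]] <- data.frame(
          start = o, end = o + m - 1L, strand = strand,
          mismatches = length(mm),
          mismatch_positions = paste(o + mm - 1L, collapse = ";"),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      mismatch_positions = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# partial-sum 3' trimming oracle: evaluate every cut point explicitly
oracle_qtrim_keep <- function(q, cutoff) {
  L <- length(q)
  sums <- vapply(seq_len(L), function(j) sum(cutoff - q[j:L]), numeric(1))
  best <- max(sums)
  if (best <= 0) return(L)
  max(which(sums == best)) - 1L   # retained length
}

# plant a spacer with nmm substitutions into a genome window; returns the
# (possibly reverse-complemented) spacer and the plus-strand truth
plant_spacer <- function(genome, start, len, strand, nmm) {
  sp <- substr(genome, start, start + len - 1L)
  if (strand == "-") sp <- rc_oracle(sp)
  mm_genome <- integer(0)
  if (nmm > 0) {
    pos <- sort(sample(2:(len - 1L), nmm))
    ch <- chars(sp)
    for (j in pos) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    sp <- paste(ch, collapse = "")
    mm_genome <- if (strand == "+") start + pos - 1L
                 else (start + len - 1L) - pos + 1L
  }
  list(spacer = sp, start = start, end = start + len - 1L, strand = strand,
       mismatch_positions = sort(mm_genome))
}

# constant-quality Phred+33 string
qual_str <- function(q, n) intToUtf8(rep(q + 33L, n))

# synthetic null pileup at constant base quality: per-site error counts
# drawn binomially and split over the three non-reference bases
null_pileup <- function(L, depth, q = 30L) {
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  err <- phred_error_prob_oracle(q)
  n_err <- rbinom(L, depth, err)
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  ref_i <- match(ref, colnames(counts))
  counts[cbind(seq_len(L), ref_i)] <- depth - n_err
  for (i in which(n_err > 0)) {
    alts <- setdiff(1:4, ref_i[i])
    add <- as.integer(rmultinom(1, n_err[i], rep(1 / 3, 3)))
    counts[i, alts] <- counts[i, alts] + add
  }
  data.frame(pos = seq_len(L), ref = ref, counts, depth = depth,
             mean_err = err, stringsAsFactors = FALSE)
}

phred_error_prob_oracle <- function(q) 10^(-q / 10)

# pileup with one variant site at alt fraction f (binomial draw)
variant_pileup <- function(f, depth, ref = "C", alt = "T", q = 30L) {
  k <- rbinom(1, depth, f)
  counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
  counts[ref] <- depth - k
  counts[alt] <- k
  cbind(data.frame(pos = 1L, ref = ref, stringsAsFactors = FALSE),
        as.data.frame(as.list(counts)),
        data.frame(depth = depth, mean_err = phred_error_prob_oracle(q)))
}
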