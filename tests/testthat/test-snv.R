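test_that("pileups tally bases, strands and qualities correctly", {
  g <- c(g = "ACGTACGTACGTACGTACGT")
  aln <- data.frame(qname = sprintf("r%d", 1:10), rname = "g", pos = 1L,
                    strand = "+", seq = unname(substr(g, 1, 10)),
                    qual = qual_str(30, 10), stringsAsFactors = FALSE)
  pu <- build_pileup(aln, g)
  expect_equal(pu$depth, rep(10L, 10))
  expect_equal(pu$ref, strsplit(substr(g, 1, 10), "")[[1]])
  # one read with a substitution shows one alternate base
  mut <- aln[1, ]; substr(mut$seq, 5, 5) <- "T"   # ref A -> T
  pu2 <- build_pileup(rbind(aln, mut), g)
  expect_equal(pu2$T[pu2$pos == 5], 1L)
  expect_equal(pu2$A[pu2$pos == 5], 10L)
  # minus-strand reads are counted in plus orientation
  neg <- data.frame(qname = "n", rname = "g", pos = 1L, strand = "-",
                    seq = rc_oracle(substr(g, 1, 10)),
                    qual = qual_str(30, 10), stringsAsFactors = FALSE)
  pu3 <- build_pileup(neg, g)
  expect_equal(pu3$depth, rep(1L, 10))
  expect_true(all(pu3[cbind(1:10, match(pu3$ref, c("A", "C", "G", "T")) +
                              2L)] == 1L))
  # overlapping reads add (hand tally: positions 6-10 covered twice)
  two <- rbind(aln[1, ], transform(aln[1, ], pos = 6L))
  pu4 <- build_pileup(two, g)
  expect_equal(pu4$depth, c(rep(1L, 5), rep(2L, 5), rep(1L, 5)))
  # low-quality bases are excluded
  lowq <- transform(aln[1, ], qual = qual_str(10, 10))
  expect_equal(nrow(build_pileup(lowq, g)), 0L)
  # alignment beyond the genome end is an error
  off <- transform(aln[1, ], pos = 15L)
  expect_error(build_pileup(off, g), "beyond")
})

test_that("the caller emits true variants with exact frequencies", {
  # all-reference pileup: no calls
  set.seed(151)
  pu <- null_pileup(200, depth = 100)
  pu$A[1] <- pu$A[1]   # no-op; keep as built
  zero <- pu; zero[, c("A", "C", "G", "T")] <- 0L
  ref_i <- match(zero$ref, c("A", "C", "G", "T"))
  zero[cbind(seq_len(nrow(zero)), ref_i + 2L)] <- 100L
  expect_equal(nrow(call_snvs(zero)), 0L)
  # 60 alt of 100 at Q30: called with frequency 0.60
  one <- variant_pileup(0.6, 100)
  one$T <- 60L; one$C <- 40L
  calls <- call_snvs(one)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$alt, "T")
  expect_equal(calls$frequency, 0.60)
  # planted fraction recovered within binomial tolerance at depth 1000
  for (f in c(0.05, 0.2, 0.5)) {
    vp <- variant_pileup(f, 1000)
    calls <- call_snvs(vp)
    expect_equal(nrow(calls), 1L)
    expect_lt(abs(calls$frequency - f), 3 * sqrt(f * (1 - f) / 1000))
  }
  # below the depth floor nothing is tested
  shallow <- variant_pileup(0.5, 5)
  expect_equal(nrow(call_snvs(shallow)), 0L)
})

test_that("family-wise false positives stay within alpha on null pileups", {
  set.seed(152)
  n_rep <- 100
  clean <- 0L
  for (r in seq_len(n_rep)) {
    pu <- null_pileup(10000, depth = 100, q = 30L)
    if (nrow(call_snvs(pu)) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 95L)
})

test_that("SNV density per ORF matches an interval-overlap oracle", {
  orfs <- data.frame(orf_id = c("a", "b"), start = c(1L, 401L),
                     end = c(300L, 700L))
  snvs <- data.frame(position = c(10L, 150L, 299L, 350L, 500L))
  d <- snv_density_per_orf(snvs, orfs)
  expect_equal(d$snvs_per_100bp, c(3 * 100 / 300, 1 * 100 / 300))
  expect_equal(d$n_snvs,
               vapply(seq_len(2), function(i)
                 sum(snvs$position >= orfs$start[i] &
                       snvs$position <= orfs$end[i]), integer(1)))
  none <- snv_density_per_orf(data.frame(position = integer(0)), orfs)
  expect_equal(none$snvs_per_100bp, c(0, 0))
})

test_that("codon effects follow the genetic code on both strands", {
  # plus strand: codons ATG GCT AAG CGA TAA
  g <- c(g = "ATGGCTAAGCGATAA")
  orf <- data.frame(orf_id = "o", start = 1L, end = 15L, strand = "+",
                    product = "x")
  # GCT -> GTT: Ala -> Val, nonsynonymous (codon position 2)
  ce <- codon_effect(g, orf, list(position = 5L, ref = "C", alt = "T"))
  expect_equal(ce$ref_codon, "GCT"); expect_equal(ce$alt_codon, "GTT")
  expect_equal(ce$ref_aa, "A"); expect_equal(ce$alt_aa, "V")
  expect_equal(ce$effect, "nonsynonymous")
  # AAG -> AAC: Lys -> Asn, nonsynonymous
  ce <- codon_effect(g, orf, list(position = 9L, ref = "G", alt = "C"))
  expect_equal(ce$ref_codon, "AAG"); expect_equal(ce$alt_codon, "AAC")
  expect_equal(paste0(ce$ref_aa, "/", ce$alt_aa), "K/N")
  # CGA -> AGA: synonymous (both Arg)
  ce <- codon_effect(g, orf, list(position = 10L, ref = "C", alt = "A"))
  expect_equal(ce$ref_codon, "CGA"); expect_equal(ce$alt_codon, "AGA")
  expect_equal(ce$effect, "synonymous")
  # a site between ORFs is noncoding
  g2 <- c(g = paste0("ATGGCTAAGCGATAA", "ACGT", "ATGGCTAAGCGATAA"))
  orfs2 <- data.frame(orf_id = c("o1", "o2"), start = c(1L, 20L),
                      end = c(15L, 34L), strand = "+", product = "x")
  expect_equal(codon_effect(g2, orfs2,
                            list(position = 17L, ref = "C",
                                 alt = "G"))$effect, "noncoding")
  # incomplete ORFs are an error
  bad <- data.frame(orf_id = "b", start = 1L, end = 14L, strand = "+",
                    product = "x")
  expect_error(codon_effect(g, bad, list(position = 5L, ref = "C",
                                         alt = "T")), "divisible")
})

test_that("minus-strand codon effects mirror the plus strand", {
  set.seed(153)
  for (i in 1:10) {
    L <- 60L
    g <- rand_dna(L)
    orf_p <- data.frame(orf_id = "p", start = 7L, end = 36L, strand = "+",
                        product = "x")
    pos <- sample(7:36, 1)
    ref <- substr(g, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ce_p <- codon_effect(c(g = g), orf_p,
                         list(position = pos, ref = ref, alt = alt))
    # same ORF on the reverse-complemented genome with mirrored coords
    g_rc <- rc_oracle(g)
    orf_m <- data.frame(orf_id = "m", start = L - 36L + 1L,
                        end = L - 7L + 1L, strand = "-", product = "x")
    pos_m <- L - pos + 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ce_m <- codon_effect(c(g = g_rc), orf_m,
                         list(position = pos_m, ref = unname(comp[ref]),
                              alt = unname(comp[alt])))
    expect_equal(ce_m$ref_codon, ce_p$ref_codon)
    expect_equal(ce_m$alt_codon, ce_p$alt_codon)
    expect_equal(c(ce_m$ref_aa, ce_m$alt_aa), c(ce_p$ref_aa, ce_p$alt_aa))
  }
})

test_that("spacer allele concordance reads the aligned base", {
  # plus-strand hit: spacer matches genome at 101..110
  spacer <- "ACGTACGTAC"
  hit <- list(start = 101L, end = 110L, strand = "+")
  # SNV at position 103 (spacer base G); alt = G
  conc <- spacer_allele_concordance(spacer, hit,
                                    list(position = 103L, ref = "A",
                                         alt = "G", frequency = 0.6))
  expect_equal(conc$allele, "alt")
  expect_equal(conc$frequency, 0.6)
  # spacer base equals the reference allele: complement frequency
  conc <- spacer_allele_concordance(spacer, hit,
                                    list(position = 103L, ref = "G",
                                         alt = "A", frequency = 0.6))
  expect_equal(conc$allele, "ref")
  expect_equal(conc$frequency, 0.4)
  # neither allele
  conc <- spacer_allele_concordance(spacer, hit,
                                    list(position = 103L, ref = "C",
                                         alt = "T", frequency = 0.6))
  expect_equal(conc$allele, "neither")
  expect_true(is.na(conc$frequency))
  # minus-strand hit: the plus-strand base is the complement of the
  # spacer base read from the 3' side
  hitm <- list(start = 101L, end = 110L, strand = "-")
  # plus-strand base at 110 = complement(spacer[1]) = T
  conc <- spacer_allele_concordance(spacer, hitm,
                                    list(position = 110L, ref = "A",
                                         alt = "T", frequency = 0.25))
  expect_equal(conc$allele, "alt")
  expect_equal(conc$frequency, 0.25)
  expect_error(spacer_allele_concordance(spacer, hit,
                                         list(position = 250L, ref = "A",
                                              alt = "G",
                                              frequency = 0.5)),
               "outside")
})

test_that("the virotope report joins spacers, hits and SNVs", {
  set.seed(154)
  cfg <- sim_config(seed = 154, phage_length = 6000, n_orfs = 6,
                    n_crispr_loci = 2, spacers_per_locus = 2,
                    planted_mismatches_per_spacer = 1, read_length = 100,
                    error_rate = 0.001)
  pg <- make_phage_genome(cfg)
  hc <- make_host_with_crispr(cfg, pg$genome)
  # plant one SNV inside the first placement
  p1 <- hc$placements[1, ]
  site <- p1$start + 5L
  ref <- substr(pg$genome, site, site)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  cfg2 <- sim_config(seed = 154, phage_length = 6000, n_orfs = 6,
                     read_length = 100, error_rate = 0.001,
                     planted_snvs = data.frame(position = site, alt = alt,
                                               fraction = 0.4))
  rr <- make_reads(pg$genome, c(synthetic_phage = 200), "DNA", cfg2)
  aln <- cbind(rr$manifest, seq = rr$reads$seq, qual = rr$reads$qual)
  calls <- call_snvs(build_pileup(aln, pg$genome),
                     contig = "synthetic_phage")
  expect_true(site %in% calls$position)
  spacers <- unlist(lapply(hc$loci, function(l)
    setNames(l$spacers$seq, l$spacers$id)))
  names(spacers) <- unlist(lapply(seq_along(hc$loci), function(li)
    sprintf("locus%d_spacer%d", li,
            seq_len(nrow(hc$loci[[li]]$spacers)))))
  hits <- match_spacers(spacers, pg$genome, max_mismatches = 3)
  rep <- make_virotope_report(spacers, hits, calls, pg$orfs, pg$genome)
  # every placement produced a row
  expect_gte(nrow(rep), nrow(hc$placements))
  # the SNV-bearing row reports the planted site
  row1 <- rep[rep$protospacer_start == p1$start &
                rep$locus == sub("_spacer.*", "", p1$spacer_id), ]
  expect_true(grepl(as.character(site), row1$snv_positions))
  expect_true(grepl(paste0(ref, "/", alt), row1$alleles))
  # rows without SNVs carry empty cells
  empties <- rep[rep$snv_positions == "–", ]
  expect_true(all(empties$alleles == "–"))
  # summary totals are consistent
  s <- summarize_virotopes(rep)
  expect_equal(s$n_snv_entries,
               s$n_synonymous + s$n_nonsynonymous + s$n_noncoding)
  # a spacer with no hit yields no row
  lone <- c(nohit = rand_dna(36))
  h0 <- match_spacers(lone, pg$genome, max_mismatches = 0)
  expect_equal(nrow(h0), 0L)
})

test_that("the reference-table summary reproduces the published counts", {
  s <- summarize_virotopes(load_virotope_table())
  expect_equal(s$n_rows, 25L)
  expect_equal(s$n_distinct_loci, 7L)
  expect_equal(s$n_rows_with_snv, 14L)
  expect_equal(s$n_rows_with_mismatch, 13L)
  expect_equal(s$n_snv_entries, 22L)
  expect_equal(s$n_synonymous, 13L)
  expect_equal(s$n_nonsynonymous, 7L)
  expect_equal(s$n_noncoding, 2L)
  expect_equal(s$n_snv_entries,
               s$n_synonymous + s$n_nonsynonymous + s$n_noncoding)
})
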