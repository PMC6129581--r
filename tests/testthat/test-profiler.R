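# a small viral taxonomy with two Caudovirales families and an outgroup
make_tree <- function() {
  taxonomy_tree(data.frame(
    id = c("root", "viruses", "caudovirales", "myoviridae", "siphoviridae",
           "podoviridae", "cyanopodo", "cyanomyo", "siphoA", "megavirales"),
    name = c("root", "Viruses", "Caudovirales", "Myoviridae",
             "Siphoviridae", "Podoviridae", "Cyanopodovirus sp.",
             "Cyanomyovirus sp.", "Siphovirus A", "Megavirales"),
    rank = c("root", "superkingdom", "order", "family", "family", "family",
             "species", "species", "species", "order"),
    parent = c("root", "root", "viruses", "caudovirales", "caudovirales",
               "caudovirales", "podoviridae", "myoviridae", "siphoviridae",
               "viruses"),
    stringsAsFactors = FALSE))
}

test_that("taxonomy validation rejects malformed trees", {
  nodes <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      rank = c("root", "species"), parent = c("a", "c"))
  expect_error(taxonomy_tree(nodes), "parent")
  two_roots <- data.frame(id = c("a", "b"), name = c("a", "b"),
                          rank = "root", parent = c("a", "b"))
  expect_error(taxonomy_tree(two_roots), "root")
})

test_that("hit recruitment uses strict coverage and E-value cutoffs", {
  h <- data.frame(query = "q", subject = "s", taxon = "cyanopodo",
                  pident = 90, length = 50, bitscore = 40,
                  evalue = c(1e-10, 1e-2, 1e-4, 1e-4),
                  coverage = c(0.64, 0.90, 0.90, 0.65))
  kept <- filter_hits(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$evalue, 1e-4)
  expect_equal(kept$coverage, 0.90)
  # idempotent
  expect_identical(filter_hits(kept), kept)
})

test_that("LCA assignment returns the deepest common ancestor", {
  tr <- make_tree()
  one <- data.frame(taxon = "cyanopodo", bitscore = 50)
  expect_equal(lca_assign(one, tr), "cyanopodo")
  two_fam <- data.frame(taxon = c("cyanopodo", "cyanomyo"),
                        bitscore = c(50, 45))
  expect_equal(lca_assign(two_fam, tr), "caudovirales")
  # all hits under the score floor: unassigned
  low <- data.frame(taxon = "cyanopodo", bitscore = 20)
  expect_true(is.na(lca_assign(low, tr)))
  # unknown taxon is an error naming it
  expect_error(lca_assign(data.frame(taxon = "nope", bitscore = 50), tr),
               "nope")
})

# path helper duplicated here so property checks don't rely on internals
tax_path_test <- function(tree, id) {
  path <- id
  while (tree$parent[match(id, tree$id)] != id) {
    id <- tree$parent[match(id, tree$id)]
    path <- c(path, id)
  }
  path
}

test_that("LCA satisfies its monotonicity properties", {
  tr <- make_tree()
  anc_of <- function(node) rev(tax_path_test(tr, node))
  set.seed(111)
  leaves <- c("cyanopodo", "cyanomyo", "siphoA")
  for (i in 1:20) {
    taxa <- sample(leaves, sample(1:3, 1), replace = TRUE)
    h <- data.frame(taxon = taxa, bitscore = 50)
    lca <- lca_assign(h, tr)
    # ancestor-or-self of every hit taxon
    for (t in taxa) expect_true(lca %in% anc_of(t))
    # duplicating a hit never changes the result
    expect_equal(lca_assign(rbind(h, h[1, ]), tr), lca)
    # a hit in a new clade never deepens the result
    h2 <- rbind(h, data.frame(taxon = "megavirales", bitscore = 50))
    lca2 <- lca_assign(h2, tr)
    expect_lte(length(tax_path_test(tr, lca2)),
               length(tax_path_test(tr, lca)))
  }
})

test_that("profiles roll up to the requested rank and standardize", {
  tr <- make_tree()
  asn <- c(rep("cyanopodo", 40), rep("cyanomyo", 30), rep("caudovirales", 10),
           rep(NA_character_, 5))
  pr <- profile(asn, tr, "order", 100)
  expect_equal(pr$relative_abundance[pr$taxon == "caudovirales"], 0.80)
  fam <- profile(asn, tr, "family", 100)
  # order-level assignments are excluded at family rank
  expect_equal(sum(fam$count), 70L)
  expect_true(all(fam$relative_abundance >= 0))
  expect_lte(sum(fam$relative_abundance), length(asn[!is.na(asn)]) / 100)
  # degenerate cases
  expect_equal(nrow(profile(character(0), tr, "family", 10)), 0L)
  one <- profile(rep("cyanopodo", 10), tr, "species", 10)
  expect_equal(one$relative_abundance, 1.0)
  expect_error(profile(asn, tr, "kingdom", 100), "unknown rank")
})

test_that("host rollup joins species assignments to host phyla", {
  tr <- make_tree()
  hm <- data.frame(taxon = c("cyanopodo", "cyanomyo"),
                   host_phylum = c("Cyanobacteria", "Cyanobacteria"))
  asn <- c(rep("cyanopodo", 10), rep("cyanomyo", 4), rep("caudovirales", 3),
           rep("siphoA", 2))
  hr <- host_rollup(asn, tr, hm)
  expect_equal(hr$count[hr$host_phylum == "Cyanobacteria"], 14L)
  # order-level and unmapped species assignments are host-unresolved
  expect_equal(hr$count[hr$host_phylum == "host-unresolved"], 5L)
  # brute-force join oracle
  expected <- table(ifelse(asn %in% hm$taxon,
                           hm$host_phylum[match(asn, hm$taxon)],
                           ifelse(tr$rank[match(asn, tr$id)] == "species",
                                  "host-unresolved", "host-unresolved")))
  expect_equal(sum(hr$count), sum(expected))
})

test_that("cellular read removal applies the 5% mismatch rule", {
  set.seed(112)
  ref_seq <- rand_dna(3000)
  refs <- c(bac = ref_seq)
  exact <- substr(ref_seq, 101, 200)
  # mismatches clustered near the 5' end so intact seeds remain downstream
  five_mm <- substr(ref_seq, 301, 400)
  for (p in 2:6)
    substr(five_mm, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(five_mm, p, p))[1]
  six_mm <- substr(ref_seq, 501, 600)
  for (p in 2:7)
    substr(six_mm, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(six_mm, p, p))[1]
  rc_read <- rc_oracle(substr(ref_seq, 701, 800))
  random <- rand_dna(100)
  reads <- data.frame(id = c("exact", "five", "six", "rc", "rand"),
                      seq = c(exact, five_mm, six_mm, rc_read, random),
                      qual = qual_str(40, 100), stringsAsFactors = FALSE)
  kept <- remove_cellular(reads, refs)
  expect_false("exact" %in% kept$id)   # exact substring removed
  expect_false("five" %in% kept$id)    # 5/100 mismatches: removed
  expect_true("six" %in% kept$id)      # 6/100 mismatches: kept
  expect_false("rc" %in% kept$id)      # minus-strand placement removed
  expect_true("rand" %in% kept$id)     # no seed hit: kept
})
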