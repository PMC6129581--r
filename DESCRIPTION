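Package: virotope
Title: Virus-Host Crossfire Analysis for Hot-Spring Phototrophic Mat
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for linking thermophilic cyanophages to
    their cyanobacterial hosts in hot-spring microbial mat metagenomes and
    metatranscriptomes. Provides a synthetic-community generator with known
    ground truth (circular phage genome with a two-strand-cluster ORF
    layout, host contigs carrying CRISPR arrays, DNA/RNA read sets with
    planted single-nucleotide variants); read quality control (adapter
    trimming, partial-sum 3' quality trimming, DUST low-complexity
    filtering); viral read profiling by lowest-common-ancestor assignment
    with host-phylum rollup; circular contig detection and viral hallmark
    screening; CRISPR repeat-spacer array detection; exhaustive
    spacer-to-protospacer matching with bounded mismatches; a quality-aware
    binomial SNV caller with codon-effect classification and spacer-allele
    concordance; and RPKM abundance with virus to host and DNA to RNA
    activity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
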