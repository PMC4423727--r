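Package: dipscaffold
Title: Diploid-Aware Scaffolding via Heterozygous Bubble Detection and
    Haplotype Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scaffolds stringently assembled diploid contig sets into two
    linear haploid scaffolds. Builds a weighted bidirected scaffold graph from
    paired-read alignments (SAM, legacy Bowtie, or BLAST tabular), detects
    heterozygous "bubbles" whose parallel paths are homologous haplotype
    contigs, trains a binary classifier on perfect bubbles to recover
    homologous pairs from imperfect ones, phases bubble chains into
    complementary haplotype groups, and emits phased scaffold FASTA. Includes
    a synthetic diploid benchmark generator (genome, error-free paired reads,
    stringent-assembly contigs with truth labels) and four phasing-quality
    metrics: contig sequencing depth, contig homogeneity, phase-group
    homogeneity, and heterogeneity between complementary phase groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    nnet,
    e1071,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
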