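Package: replichar
Title: Characterisation and Classification of Bacterial Replicons in Multipartite Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the replicons of multipartite bacterial
    genomes and decide whether a secondary replicon is a plasmid, megaplasmid,
    chromid or secondary chromosome. Reads multi-record GenBank and FASTA
    input, computes per-replicon G+C content and sliding-window GC-skew
    profiles with cumulative-skew extrema, codon-usage tables with tie-aware
    Spearman rank correlation and RSCU, COG functional-category profiles,
    taxon-rank gene-specificity scores from tabular homology hits, terminal
    inverted repeat (TIR) detection by seed-and-extend banded alignment,
    motif scanning, k-mer dot plots and a replication-marker survey. A
    synthetic multipartite-genome generator with closed-form expected
    statistics makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
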