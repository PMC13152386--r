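# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no binary fixtures.

# i.i.d. random DNA with optionally asymmetric G/C (for skew constructions)
rand_dna <- function(n, pA = 0.25, pC = 0.25, pG = 0.25, pT = 0.25) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(pA, pC, pG, pT)), collapse = "")
}

# mutate exactly k positions of a sequence to a different base
mutate_k <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# a replicon whose single CDS is the given coding sequence (plus strand)
one_cds_replicon <- function(coding, id = "r1", flank = 30L) {
  pre <- rand_dna(flank); post <- rand_dna(flank)
  cds <- data.frame(locus_tag = paste0(id, "_1"),
                    start = flank + 1L, end = flank + nchar(coding),
                    strand = "+", partial = FALSE,
                    product = NA_character_, translation = NA_character_)
  replicon(id, paste0(pre, coding, post), "linear", cds)
}

# small two-replicon genome with hand-placed CDS on both strands
tiny_genome <- function() {
  s1 <- rand_dna(600)
  cds1 <- data.frame(
    locus_tag = sprintf("A_%03d", 1:5),
    start = c(11L, 101L, 201L, 301L, 401L),
    end = c(70L, 160L, 290L, 390L, 490L),
    strand = c("+", "-", "+", "-", "+"),
    partial = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    product = c("hypothetical protein", "DNA gyrase subunit A gyrA",
                NA, NA, NA),
    translation = c("MAAA", NA, "MCCC", NA, NA))
  s2 <- rand_dna(300)
  cds2 <- data.frame(
    locus_tag = sprintf("B_%03d", 1:3),
    start = c(21L, 101L, 201L), end = c(80L, 190L, 260L),
    strand = c("+", "+", "-"), partial = FALSE,
    product = NA_character_, translation = NA_character_)
  genome("tiny", list(replicon("repA", s1, "linear", cds1),
                      replicon("repB", s2, "circular", cds2)),
         strain = "tiny", genus = "G", family = "F")
}

# independent Spearman oracle: explicit rank-then-Pearson via stats::cor
oracle_spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# quick hand grouping for specificity tests
toy_grouping <- function() {
  data.frame(genome_id = c("F", "G1", "G2", "O1", "O2", "O3"),
             strain = c("F", "G1", "G2", "O1", "O2", "O3"),
             genus = c("gen", "gen", "gen", "out1", "out2", "out3"),
             family = c("fam", "fam", "fam", "ofam", "ofam", "ofam"))
}
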