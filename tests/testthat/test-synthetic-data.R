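test_that("the generator is deterministic under a fixed seed", {
  specs <- list(replicon_spec("X", 20000L, n_cds = 15L,
                              cds_length_mean = 100, cds_length_sd = 10,
                              tir = list(length = 800L, mutation_rate = 0.001)))
  o1 <- generate_genome(specs, seed = 91)
  o2 <- generate_genome(specs, seed = 91)
  expect_identical(o1$genome$replicons$X$sequence, o2$genome$replicons$X$sequence)
  expect_identical(o1$annotations, o2$annotations)
  expect_identical(o1$hits, o2$hits)
  o3 <- generate_genome(specs, seed = 92)
  expect_false(identical(o1$genome$replicons$X$sequence,
                         o3$genome$replicons$X$sequence))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(generate_genome(list(replicon_spec("X", 8000L, n_cds = 5L,
                                               cds_length_mean = 60,
                                               cds_length_sd = 5)), seed = 1))
  expect_equal(runif(2), a[2:3])  # stream continues where it left off
})

test_that("an infeasible spec errors before writing any file", {
  dir <- withr::local_tempdir()
  out_dir <- file.path(dir, "out")
  specs <- list(replicon_spec("X", 5000L, n_cds = 100L,
                              cds_length_mean = 100, cds_length_sd = 5))
  expect_error(generate_genome(specs, seed = 1, out_dir = out_dir), "infeasible")
  expect_false(dir.exists(out_dir))
})

test_that("a zero-divergence TIR is recovered at exactly 100% identity", {
  out <- generate_genome(list(
    replicon_spec("X", 40000L, n_cds = 20L, cds_length_mean = 80,
                  cds_length_sd = 8,
                  tir = list(length = 1500L, mutation_rate = 0))), seed = 93)
  expect_equal(out$truth$tir$X$identity, 100)
  t <- find_tir(out$genome$replicons$X, window = 500L)
  expect_equal(t$percent_identity, 100)
})

test_that("emitted files parse back to the generated truth", {
  dir <- withr::local_tempdir()
  out <- generate_genome(preset_embleya(0.1), seed = 94, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("genome.gbk", "genome.fasta",
                                               "annotations.tsv", "hits.tsv",
                                               "grouping.tsv")))))
  g2 <- read_genome_genbank(file.path(dir, "genome.gbk"))
  expect_equal(names(g2$replicons), names(out$genome$replicons))
  for (id in names(g2$replicons)) {
    expect_identical(g2$replicons[[id]]$sequence,
                     out$genome$replicons[[id]]$sequence)
    expect_equal(nrow(g2$replicons[[id]]$cds),
                 nrow(out$genome$replicons[[id]]$cds))
  }
  fa <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(unname(fa["CHR"]), out$genome$replicons$CHR$sequence)
  ann <- read_cog_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(out$annotations))
  h <- read_hit_table(file.path(dir, "hits.tsv"), out$subject_to_genome)
  expect_equal(nrow(h), nrow(out$hits))
})

test_that("measured statistics match closed-form predictions", {
  sp <- replicon_spec("X", 500000L, target_gc = 0.716, n_cds = 2000L,
                      cds_length_mean = 60, cds_length_sd = 5,
                      cog_mixture = c(E = 0.4, K = 0.3, L = 0.2, S = 0.1),
                      tir = list(length = 2000L, mutation_rate = 0.0005))
  pred <- predicted_statistics(sp)
  out <- generate_genome(list(sp), seed = 95)
  r <- out$genome$replicons$X

  expect_lt(abs(gc_content(r$sequence) - pred$gc), 0.01)

  tab <- codon_counts(r)
  expect_lt(max(abs(tab$percentages - pred$codon_percent[names(tab$percentages)])),
            0.75)

  expect_equal(out$truth$tir$X$identity, pred$tir_identity)

  prof <- cog_profile(r, out$annotations)
  mix <- pred$cog_percent
  expect_lt(max(abs(prof$category_percent[names(mix)] - mix), na.rm = TRUE), 3)

  # per-tier expected specificity scores are ordered as the tiers nest
  s <- pred$specificity
  strain <- s[s$level == "strain", ]
  expect_true(strain$score[strain$tier == "strain-unique"] >
              strain$score[strain$tier == "genus-core"])
  expect_true(strain$score[strain$tier == "genus-core"] >
              strain$score[strain$tier == "universal"])
})

test_that("generated annotations and tiers are internally consistent", {
  out <- generate_genome(preset_embleya(0.1), seed = 96)
  for (id in names(out$genome$replicons)) {
    r <- out$genome$replicons[[id]]
    seqs <- cds_sequences(r)
    expect_true(all(startsWith(seqs, "ATG")))
    expect_true(all(substring(seqs, nchar(seqs) - 2L) %in%
                      c("TAA", "TAG", "TGA")))
    expect_true(all(nchar(seqs) %% 3L == 0L))
  }
  # every gene appears exactly once in the tier table and presence matrix
  tags <- unlist(lapply(out$genome$replicons, function(r) r$cds$locus_tag),
                 use.names = FALSE)
  expect_setequal(out$truth$gene_tier$gene_id, tags)
  expect_setequal(rownames(out$truth$presence), tags)
  expect_true(all(out$truth$presence[, "FOCAL"]))
})
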