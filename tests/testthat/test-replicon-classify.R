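marker_replicon <- function(products, gap_genes = 0L, id = "m") {
  n <- length(products) + gap_genes
  prods <- c(products[1L], rep("hypothetical protein", gap_genes),
             products[-1L])
  cds <- data.frame(locus_tag = sprintf("%s_%03d", id, seq_len(n)),
                    start = seq(1L, by = 100L, length.out = n),
                    end = seq(90L, by = 100L, length.out = n),
                    strand = "+", partial = FALSE, product = prods,
                    translation = NA_character_)
  replicon(id, rand_dna(100L * n + 10L), "linear", cds)
}

test_that("marker co-occurrence drives the origin call", {
  set.seed(61)
  r <- marker_replicon(c("chromosomal replication initiation protein dnaA",
                         "DNA polymerase III beta sliding clamp dnaN",
                         "partitioning protein parA",
                         "partitioning protein parB"))
  expect_equal(survey_markers(r)$origin_call, "chromosomal")

  r <- marker_replicon(c("plasmid replication iteron protein rep1",
                         "plasmid replicative DNA helicase rep2"))
  expect_equal(survey_markers(r)$origin_call, "plasmid")

  # dnaN with a distant parA and no dnaA
  r <- marker_replicon(c("DNA polymerase III beta sliding clamp dnaN",
                         "partitioning protein parA"), gap_genes = 10L)
  sv <- survey_markers(r)
  expect_equal(sv$origin_call, "incomplete-chromosomal")

  # dnaA and dnaN separated beyond the cluster span are not chromosomal
  r <- marker_replicon(c("chromosomal replication initiation protein dnaA",
                         "DNA polymerase III beta sliding clamp dnaN"),
                       gap_genes = 10L)
  expect_false(survey_markers(r)$origin_call == "chromosomal")

  rn <- replicon("none", rand_dna(1000), "linear")
  expect_warning(sv <- survey_markers(rn), "no CDS")
  expect_equal(sv$origin_call, "none")
})

fv <- function(size, delta_gc, codon_rho, has_core, origin,
               is_chr = FALSE, id = "r") {
  structure(list(replicon_id = id, is_chromosome = is_chr, size_bp = size,
                 size_ratio_to_chromosome = 0.5, delta_gc = delta_gc,
                 codon_rho = codon_rho, cog_rho = NA_real_,
                 has_core_genes = has_core, origin_call = origin,
                 genus_specific_profile = NA_character_),
            class = "feature_vector")
}

test_that("the rubric assigns each canonical column its label", {
  # chromid: core genes, chromosome-like composition, plasmid replication
  expect_equal(classify(fv(9e5, 0.1, 0.97, TRUE, "plasmid"))$label, "chromid")
  # secondary chromosome: same but incomplete-chromosomal replication
  expect_equal(classify(fv(9e5, 0.1, 0.97, TRUE, "incomplete-chromosomal"))$label,
               "secondary chromosome")
  # below the size bound: plasmid
  expect_equal(classify(fv(200000, 2.5, 0.7, FALSE, "plasmid"))$label, "plasmid")
  # large but no core genes: megaplasmid
  expect_equal(classify(fv(9e5, 2.5, 0.7, FALSE, "none"))$label, "megaplasmid")
  # largest replicon is always the chromosome
  expect_equal(classify(fv(7e6, 0, 1, TRUE, "chromosomal", is_chr = TRUE))$label,
               "chromosome")
  # conflicting evidence (core genes, divergent composition) -> megaplasmid
  cl <- classify(fv(9e5, 3.0, 0.7, TRUE, "plasmid"))
  expect_equal(cl$label, "megaplasmid")
  expect_true(any(grepl("conflict", cl$rationale)))
  # every call carries a non-empty rationale
  expect_gt(length(cl$rationale), 0L)
})

test_that("raising rho_min never moves labels toward chromid/secondary chromosome", {
  vals <- expand.grid(rho = c(0.5, 0.85, 0.92, 0.99),
                      dgc = c(0.1, 1.5), core = c(TRUE, FALSE),
                      origin = c("plasmid", "incomplete-chromosomal", "none"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vals))) {
    v <- fv(9e5, vals$dgc[i], vals$rho[i], vals$core[i], vals$origin[i])
    lo <- classify(v, classification_thresholds(rho_min = 0.9))$label
    hi <- classify(v, classification_thresholds(rho_min = 0.95))$label
    chromlike <- c("chromid", "secondary chromosome")
    if (hi %in% chromlike) expect_true(lo %in% chromlike)
  }
})

test_that("feature vectors reproduce generator truth for self and secondary", {
  out <- generate_genome(preset_embleya(0.15), seed = 71)
  cfg <- default_config(thresholds = classification_thresholds(
    megaplasmid_min = 350000 * 0.15))
  b <- suppressWarnings(run_all(out$genome, out$annotations, out$hits,
                                out$grouping, out$core_genes,
                                out$query_replicon, focal_genome = "FOCAL",
                                config = cfg))
  chr_fv <- b$feature_vectors$CHR
  expect_true(chr_fv$is_chromosome)
  expect_equal(chr_fv$size_ratio_to_chromosome, 1)
  expect_equal(chr_fv$delta_gc, 0)
  expect_equal(chr_fv$codon_rho, 1)
  sec_fv <- b$feature_vectors$EEC1
  expect_lt(sec_fv$delta_gc, 1)
  expect_gt(sec_fv$codon_rho, 0.9)
  expect_true(sec_fv$has_core_genes)
  expect_equal(sec_fv$origin_call, "incomplete-chromosomal")
  expect_equal(b$classes$EEC1$label, "secondary chromosome")
})
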