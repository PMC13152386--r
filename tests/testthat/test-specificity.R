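test_that("presence thresholding follows the homology-search defaults", {
  hit <- function(pid, cov, ev) data.frame(
    query_id = "q", subject_id = "s", percent_identity = pid,
    alignment_length = cov * 2, evalue = ev, bitscore = 100,
    query_length = 200, genome_id = "g")
  m <- presence_from_hits(hit(30, 60, 1e-10))
  expect_true(m["q", "g"])
  m <- presence_from_hits(hit(20, 60, 1e-10))
  expect_false(m["q", "g"])
  m <- presence_from_hits(hit(30, 40, 1e-10))   # coverage 40% < 50%
  expect_false(m["q", "g"])
  m <- presence_from_hits(hit(30, 60, 0.01))    # evalue above 0.001
  expect_false(m["q", "g"])
  # no query length: coverage test skipped with a warning
  h <- hit(30, 10, 1e-10); h$query_length <- NA_real_
  expect_warning(m <- presence_from_hits(h), "coverage")
  expect_true(m["q", "g"])
})

test_that("presence matrix on the synthetic pangenome equals generator truth", {
  out <- generate_genome(list(
    replicon_spec("X", 90000L, n_cds = 300L, cds_length_mean = 60,
                  cds_length_sd = 5,
                  tier_mixture = c("strain-unique" = 0.25, "genus-core" = 0.25,
                                   "family-core" = 0.25, "universal" = 0.25))),
    seed = 33)
  truth <- out$truth$presence
  got <- presence_from_hits(out$hits, queries = rownames(truth),
                            genomes = colnames(truth))
  non_focal <- setdiff(colnames(truth), "FOCAL")
  expect_identical(got[, non_focal], truth[, non_focal])
})

test_that("specificity score: boundaries, hand value and monotonicity", {
  expect_equal(specificity_score(1, 0), 1.0)
  expect_equal(specificity_score(1, 1), 0.5)
  expect_equal(specificity_score(0.5, 0.25), 1 / 3)
  expect_error(specificity_score(0, 0), "undefined")
  # alternative rendering
  expect_equal(specificity_score(1, 0, formula = "alt"), 0.5)
  expect_equal(specificity_score(1, 1, formula = "alt"), 1 / 3)
  # bounds and monotonicity on a grid
  grid <- expand.grid(fA = seq(0.1, 1, 0.1), fB = seq(0, 1, 0.1))
  s <- specificity_score(grid$fA, grid$fB)
  expect_true(all(s >= 0 & s <= 1))
  for (fa in seq(0.1, 1, 0.1)) {
    sc <- specificity_score(rep(fa, 11), seq(0, 1, 0.1))
    expect_true(all(diff(sc) < 0))          # decreasing in fB
  }
  for (fb in seq(0, 1, 0.1)) {
    sc <- specificity_score(seq(0.1, 1, 0.1), rep(fb, 10))
    expect_true(all(diff(sc) > 0))          # increasing in fA
  }
})

test_that("score_all computes group frequencies per level", {
  pres <- matrix(FALSE, 2, 6, dimnames = list(c("p_only", "p_all"),
                                              toy_grouping()$genome_id))
  pres["p_all", ] <- TRUE
  recs <- score_all(pres, toy_grouping(), "strain", focal_genome = "F",
                    query_replicon = c(p_only = "r1", p_all = "r1"))
  expect_equal(recs$score[recs$protein_id == "p_only"], 1.0)  # fA=1, fB=0
  expect_equal(recs$score[recs$protein_id == "p_all"], 0.5)
  for (lv in c("genus", "family")) {
    recs <- score_all(pres, toy_grouping(), lv, "F",
                      c(p_only = "r1", p_all = "r1"))
    expect_equal(recs$score[recs$protein_id == "p_all"], 0.5)
  }
  # a grouping with no group B is an error
  gr1 <- toy_grouping(); gr1$genus <- "gen"; gr1$family <- "fam"
  expect_error(score_all(pres, gr1, "genus", "F"), "group B")
})

test_that("scores on the synthetic pangenome equal the closed form from truth", {
  out <- generate_genome(list(
    replicon_spec("X", 60000L, n_cds = 200L, cds_length_mean = 60,
                  cds_length_sd = 5,
                  tier_mixture = c("strain-unique" = 0.25, "genus-core" = 0.25,
                                   "family-core" = 0.25, "universal" = 0.25))),
    seed = 34)
  pres <- out$truth$presence
  gr <- out$grouping
  recs <- score_all(pres, gr, "genus", "FOCAL", out$query_replicon)
  inA <- gr$genus == gr$genus[1L]
  fA <- rowMeans(pres[, gr$genome_id[inA], drop = FALSE])
  fB <- rowMeans(pres[, gr$genome_id[!inA], drop = FALSE])
  expect_equal(recs$fA, unname(fA))
  expect_equal(recs$fB, unname(fB))
  expect_equal(recs$score, unname(fA^2 / (fA + fB)))
})

test_that("per-tier strain-level medians are ordered by conservation depth", {
  out <- generate_genome(list(
    replicon_spec("X", 250000L, n_cds = 800L, cds_length_mean = 60,
                  cds_length_sd = 5,
                  tier_mixture = c("strain-unique" = 0.25, "genus-core" = 0.25,
                                   "family-core" = 0.25, "universal" = 0.25))),
    seed = 35)
  recs <- score_all(presence_from_hits(out$hits,
                                       queries = rownames(out$truth$presence),
                                       genomes = out$grouping$genome_id),
                    out$grouping, "strain", "FOCAL", out$query_replicon)
  med <- vapply(split(recs$score, out$truth$gene_tier$tier[
    match(recs$protein_id, out$truth$gene_tier$gene_id)]), stats::median,
    numeric(1))
  expect_gt(med[["strain-unique"]], med[["genus-core"]])
  expect_gt(med[["genus-core"]], med[["family-core"]])
  expect_gt(med[["family-core"]], med[["universal"]])
})

test_that("summaries report type-7 quartiles per replicon and level", {
  recs <- data.frame(protein_id = sprintf("p%d", 1:6),
                     replicon_id = c(rep("A", 3), rep("B", 3)),
                     level = "strain",
                     fA = 1, fB = 0,
                     score = c(1, 1, 1, 0.5, 0.75, 1.0))
  s <- summarize_by_replicon(recs)
  expect_equal(s$median[s$replicon_id == "A"], 1)
  expect_equal(s$q1[s$replicon_id == "A"], 1)
  expect_equal(s$median[s$replicon_id == "B"], 0.75)
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_equal(s$n, c(3L, 3L))
})

test_that("genus-tier replicon outranks strain-tier replicon at genus level", {
  out <- generate_genome(list(
    replicon_spec("SEC", 90000L, n_cds = 300L, cds_length_mean = 60,
                  cds_length_sd = 5,
                  tier_mixture = c("genus-core" = 0.8, "strain-unique" = 0.2)),
    replicon_spec("PLS", 90000L, n_cds = 300L, cds_length_mean = 60,
                  cds_length_sd = 5,
                  tier_mixture = c("strain-unique" = 0.9, "genus-core" = 0.1))),
    seed = 36)
  pres <- presence_from_hits(out$hits, queries = rownames(out$truth$presence),
                             genomes = out$grouping$genome_id)
  recs <- score_all(pres, out$grouping, "genus", "FOCAL", out$query_replicon)
  s <- summarize_by_replicon(recs)
  expect_gt(s$median[s$replicon_id == "SEC"], s$median[s$replicon_id == "PLS"])
})
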