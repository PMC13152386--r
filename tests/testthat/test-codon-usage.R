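test_that("codon counting reads eligible CDS in frame", {
  r <- one_cds_replicon("ATGGCCTAA")
  t <- codon_counts(r)
  expect_equal(unname(t$counts[c("ATG", "GCC", "TAA")]), c(1L, 1L, 1L))
  expect_equal(t$total_codons, 3L)
  expect_equal(sum(t$percentages), 100)

  r <- one_cds_replicon("ATGNNNTAA")
  t <- codon_counts(r)
  expect_equal(t$total_codons, 2L)
  expect_equal(t$n_ambiguous, 1L)

  # partial and frame-broken CDS are excluded but counted
  r <- tiny_genome()$replicons$repA
  t <- codon_counts(r)
  expect_equal(t$n_cds_used + t$n_cds_skipped, nrow(r$cds))
})

test_that("stop-codon toggle removes stops from the table", {
  r <- one_cds_replicon("ATGGCCTAA")
  t <- codon_counts(r, include_stops = FALSE)
  expect_false("TAA" %in% names(t$counts))
  expect_equal(t$total_codons, 2L)
})

test_that("observed codon percentages recover generating weights within 0.5 points", {
  set.seed(11)
  w <- gc_codon_weights(0.716)
  body <- setdiff(names(w), c("TAA", "TAG", "TGA"))
  wb <- w[body] / sum(w[body])
  n <- 60000L
  coding <- paste(sample(body, n, replace = TRUE, prob = wb), collapse = "")
  r <- one_cds_replicon(coding)
  r$cds$partial <- FALSE
  t <- codon_counts(r, include_stops = FALSE)
  expected <- 100 * wb[names(t$percentages)]
  expect_lt(max(abs(t$percentages - expected)), 0.5)
})

test_that("spearman_rho handles monotone, reversed and tied inputs", {
  expect_equal(spearman_rho(1:10, 1:10), 1.0)
  expect_equal(spearman_rho(1:10, 10:1), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(10, 20, 20, 40)), 1.0)
  expect_warning(expect_true(is.na(spearman_rho(rep(1, 5), 1:5))), "zero-variance")
})

test_that("spearman_rho equals the rank-then-Pearson oracle within 1e-12", {
  set.seed(12)
  worst <- 0
  for (i in 1:1000) {
    x <- sample(100, 64, replace = TRUE)   # replacement forces ties
    y <- sample(100, 64, replace = TRUE)
    worst <- max(worst, abs(spearman_rho(x, y) - oracle_spearman(x, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("codon correlation: identical weights high, inverted ranks negative", {
  set.seed(13)
  w <- gc_codon_weights(0.716)
  body <- setdiff(names(w), c("TAA", "TAG", "TGA"))
  wb <- w[body] / sum(w[body])
  draw <- function(weights, n = 55000L)
    one_cds_replicon(paste(sample(names(weights), n, TRUE, weights), collapse = ""))
  r1 <- draw(wb); r2 <- draw(wb)
  t1 <- codon_counts(r1, include_stops = FALSE)
  t2 <- codon_counts(r2, include_stops = FALSE)
  t1$replicon_id <- "a"; t2$replicon_id <- "b"
  rho <- codon_correlation(list(t1, t2))
  expect_gte(rho["a", "b"], 0.95)
  expect_equal(diag(rho), c(a = 1, b = 1))
  expect_equal(rho, t(rho))

  wi <- inverted_rank_weights(wb)
  r3 <- draw(wi)
  t3 <- codon_counts(r3, include_stops = FALSE); t3$replicon_id <- "c"
  rho <- codon_correlation(list(t1, t3))
  expect_lt(rho["a", "c"], 0)
})

test_that("correlation is invariant to table order and excludes empty tables", {
  set.seed(14)
  r1 <- one_cds_replicon(rand_dna(3000 * 3)); r1$id <- "a"
  r2 <- one_cds_replicon(rand_dna(3000 * 3)); r2$id <- "b"
  r3 <- one_cds_replicon(rand_dna(3000 * 3)); r3$id <- "c"
  ts <- lapply(list(r1, r2, r3), codon_counts)
  for (i in 1:3) ts[[i]]$replicon_id <- c("a", "b", "c")[i]
  m1 <- codon_correlation(ts)
  m2 <- codon_correlation(rev(ts))
  expect_equal(m1["a", "c"], m2["a", "c"])

  empty <- codon_counts(replicon("e", rand_dna(100), "linear"))
  expect_warning(m3 <- codon_correlation(c(ts, list(empty))), "empty")
  expect_equal(dim(m3), c(3L, 3L))
})

test_that("RSCU equals hand-computed synonym-family ratios", {
  r <- one_cds_replicon("ATGGCATAA")
  t <- codon_counts(r)
  t$counts[c("GCA", "GCC", "GCG", "GCT")] <- c(4L, 0L, 0L, 0L)
  v <- rscu(t)
  expect_equal(unname(v[c("GCA", "GCC", "GCG", "GCT")]), c(4, 0, 0, 0))
  # uniform usage in every family gives RSCU 1 everywhere
  t$counts[] <- 2L
  v <- rscu(t)
  expect_true(all(v == 1))
  # hand-computed mixed family: Lys = {AAA, AAG}
  t$counts[] <- 0L
  t$counts[c("AAA", "AAG")] <- c(3L, 1L)
  v <- rscu(t)
  expect_equal(unname(v[c("AAA", "AAG")]), c(1.5, 0.5))
})

test_that("replicon counts equal the sum of per-CDS counts", {
  set.seed(15)
  cds1 <- "ATGGCCGGCTAA"; cds2 <- "ATGAAATTTCCCTAG"
  r12 <- replicon("x", paste0(rand_dna(10), cds1, rand_dna(5), cds2, rand_dna(10)),
                  "linear",
                  data.frame(locus_tag = c("x1", "x2"),
                             start = c(11L, 11L + nchar(cds1) + 5L),
                             end = c(10L + nchar(cds1),
                                     10L + nchar(cds1) + 5L + nchar(cds2)),
                             strand = "+", partial = FALSE))
  whole <- codon_counts(r12)$counts
  solo <- function(s) codon_counts(one_cds_replicon(s))$counts
  expect_equal(whole, solo(cds1) + solo(cds2))
})
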