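tir_replicon <- function(tir_len = 5000L, core_len = 20000L, n_mut = 0L,
                         gc = 0.5, id = "t") {
  L <- rand_dna(tir_len, pC = gc / 2, pG = gc / 2,
                pA = (1 - gc) / 2, pT = (1 - gc) / 2)
  Lr <- if (n_mut > 0L) mutate_k(L, n_mut) else L
  core <- rand_dna(core_len)
  replicon(id, paste0(L, core, revcomp(Lr)), "linear")
}

test_that("a perfect implanted TIR is recovered whole at 100% identity", {
  set.seed(51)
  r <- tir_replicon(5000L, 20000L, 0L)
  rep_tir <- find_tir(r, window = 1000L)
  expect_false(is.null(rep_tir))
  expect_equal(rep_tir$percent_identity, 100)
  expect_lte(abs(rep_tir$length - 5000L), 1000L)
  expect_equal(rep_tir$left_interval[1], 1L)
  expect_equal(rep_tir$right_interval[2], r$length)
  # bookkeeping
  expect_equal(rep_tir$matches + rep_tir$mismatches + rep_tir$indels,
               rep_tir$length)
})

test_that("five point mutations shift identity by exactly their count", {
  set.seed(52)
  r <- tir_replicon(5000L, 20000L, 5L)
  rep_tir <- find_tir(r, window = 1000L)
  expect_false(is.null(rep_tir))
  expect_lte(abs(rep_tir$length - 5000L), 1000L)
  expect_lt(abs(rep_tir$percent_identity - 99.9), 0.05)
})

test_that("recovered identity tracks the implanted divergence across rates", {
  set.seed(53)
  L <- 5000L
  last_identity <- 100.01
  for (rate in c(0, 0.0005, 0.005, 0.05)) {
    k <- round(rate * L)
    r <- tir_replicon(L, 15000L, k)
    rep_tir <- find_tir(r, min_identity = 90, window = 1000L)
    expect_false(is.null(rep_tir))
    expect_lte(abs(rep_tir$length - L), 1000L)
    expect_lt(abs(rep_tir$percent_identity - 100 * (1 - k / L)), 0.1)
    # monotone degradation with the mutation rate
    expect_lte(rep_tir$percent_identity, last_identity)
    last_identity <- rep_tir$percent_identity
  }
})

test_that("unrelated ends yield no TIR; circular replicons are rejected", {
  set.seed(54)
  r <- replicon("x", rand_dna(30000), "linear")
  expect_null(find_tir(r))
  rc <- replicon("c", rand_dna(30000), "circular")
  expect_error(find_tir(rc), "linear")
})

test_that("detection is symmetric under reverse complement of the replicon", {
  set.seed(55)
  r <- tir_replicon(3000L, 12000L, 2L)
  fwd <- find_tir(r, window = 500L)
  rev_ <- find_tir(replicon("t_rc", revcomp(r$sequence), "linear"),
                   window = 500L)
  expect_false(is.null(fwd)); expect_false(is.null(rev_))
  expect_equal(rev_$length, fwd$length)
  expect_equal(rev_$percent_identity, fwd$percent_identity)
})

test_that("banded extension score equals an edit-distance oracle on short pairs", {
  set.seed(56)
  for (i in 1:10) {
    a_str <- rand_dna(1500)
    # substitutions plus a couple of short indels, all well inside the band
    b_chars <- strsplit(mutate_k(a_str, 15L), "")[[1]]
    b_chars <- append(b_chars, c("A", "C"), after = 700L)
    b_chars <- b_chars[-c(200L, 201L, 202L)]
    b_str <- paste(b_chars, collapse = "")
    n <- min(nchar(a_str), nchar(b_str))
    al <- replichar:::banded_align_ops(strsplit(a_str, "")[[1]][1:n],
                                       strsplit(b_str, "")[[1]][1:n],
                                       band = 50L)
    expect_equal(al$score, as.integer(utils::adist(substr(a_str, 1, n),
                                                   substr(b_str, 1, n))))
  }
})

test_that("shared terminal blocks between replicons are found from either end", {
  set.seed(57)
  block <- rand_dna(3000)
  ra <- replicon("a", paste0(block, rand_dna(15000)), "linear")
  rb <- replicon("b", paste0(rand_dna(12000), revcomp(block)), "linear")
  eh <- end_homology(ra, "left", rb, "right", window = 500L)
  expect_false(is.null(eh))
  expect_lte(abs(eh$length - 3000L), 500L)
  expect_equal(eh$percent_identity, 100)
  expect_equal(eh$interval_a[1], 1L)
  expect_equal(eh$interval_b[2], rb$length)

  # diverged copies: identity equals the implanted divergence
  k <- round(0.0005 * 3000)
  rb2 <- replicon("b2", paste0(rand_dna(12000), revcomp(mutate_k(block, k))),
                  "linear")
  eh2 <- end_homology(ra, "left", rb2, "right", window = 500L)
  expect_lt(abs(eh2$percent_identity - 100 * (1 - k / 3000)), 0.05)
})

test_that("motif scanning: palindromes, implants and mismatch counting", {
  set.seed(58)
  parS <- "GTTTCACGTGAAAC"
  expect_identical(revcomp(parS), parS)
  bg <- rand_dna(20000)
  pos <- c(2001L, 9001L, 15001L)
  for (p in pos) substr(bg, p, p + nchar(parS) - 1L) <- parS
  r <- replicon("m", bg, "linear")
  hits <- find_motif(r, parS, max_mismatches = 0L)
  expect_true(hits$palindromic)
  expect_equal(hits$hits$position, pos)
  expect_true(all(hits$hits$mismatches == 0L))

  # non-palindromic motif scans both strands
  mot <- "GATTACAGATTACA"
  bg2 <- rand_dna(5000)
  substr(bg2, 1001L, 1014L) <- mot
  substr(bg2, 3001L, 3014L) <- revcomp(mot)
  r2 <- replicon("m2", bg2, "linear")
  h2 <- find_motif(r2, mot)
  expect_equal(h2$hits$position, c(1001L, 3001L))
  expect_equal(h2$hits$strand, c("+", "-"))

  # one-mismatch copy reported with mismatches == 1
  one_off <- mot
  substr(one_off, 7L, 7L) <- "T"
  bg3 <- rand_dna(3000)
  substr(bg3, 501L, 514L) <- one_off
  h3 <- find_motif(replicon("m3", bg3, "linear"), mot, max_mismatches = 1L)
  expect_true(any(h3$hits$position == 501L & h3$hits$mismatches == 1L))

  # motif longer than the sequence finds nothing
  h4 <- find_motif(replicon("m4", "ACGT", "linear"), parS)
  expect_equal(nrow(h4$hits), 0L)
})

test_that("dot plots show self-diagonal, reverse anti-diagonal and shared blocks", {
  set.seed(59)
  s <- rand_dna(2000)
  dp <- dotplot_kmers(s, s, k = 12L)
  diag_pts <- dp$points[dp$points$strand == "+", ]
  expect_true(all(seq_len(2000 - 11) %in%
                    diag_pts$pos_a[diag_pts$pos_a == diag_pts$pos_b]))

  dp2 <- dotplot_kmers(s, revcomp(s), k = 12L)
  revpts <- dp2$points[dp2$points$strand == "-", ]
  expect_gt(nrow(revpts), 1900)
  # anti-diagonal: pos_a + pos_b is constant for the mirrored match
  expect_true(any(revpts$pos_a + revpts$pos_b == 2000 - 12 + 2))

  block <- rand_dna(800)
  sa <- paste0(rand_dna(500), block, rand_dna(500))
  sb <- paste0(rand_dna(1200), block, rand_dna(300))
  dp3 <- dotplot_kmers(sa, sb, k = 16L)
  fwd <- dp3$points[dp3$points$strand == "+", ]
  expect_gte(nrow(fwd), 800 - 16)
  offs <- fwd$pos_b - fwd$pos_a
  main_off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  expect_equal(main_off, 700L)  # 1200 - 500 by construction
  run <- fwd[offs == main_off, ]
  expect_lte(min(run$pos_a), 510L)
  expect_gte(max(run$pos_a), 500L + 800L - 16L - 10L)
})

test_that("point caps thin deterministically and keep the total", {
  set.seed(60)
  s <- paste(rep("ACGTACGTACGTACGT", 200), collapse = "")  # highly repetitive
  dp <- dotplot_kmers(s, s, k = 8L, max_points = 1000L)
  expect_lte(nrow(dp$points), 1000L)
  expect_gt(dp$n_total, 1000L)
  dp2 <- dotplot_kmers(s, s, k = 8L, max_points = 1000L)
  expect_identical(dp$points, dp2$points)
})
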