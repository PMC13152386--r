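# Terminal inverted repeat (TIR) detection and terminal homology between
# replicons, by deterministic seed-and-extend:
#   1. seed: an exact shared word of length seed_len between the left end and
#      the reverse complement of the right end, within the first max_scan
#      bases of each;
#   2. extend: banded unit-cost alignment (match 0, mismatch/indel 1) of the
#      two inward-reading ends, grown geometrically until the trailing-window
#      identity drops below min_identity or half the replicon is consumed;
#   3. trim: the alignment is cut at the column maximising
#      matches - lambda * differences with lambda = min_identity/(100 -
#      min_identity), i.e. the last point at which extension still pays at
#      the identity threshold. This places the boundary at the end of the
#      repeat instead of partway into unrelated flanking sequence, which a
#      literal "global identity still above threshold" cut would include.
# Identity counts indels as differences (column-wise) and is reported over
# the kept columns. Coordinates are 1-based inclusive on the forward strand.

# Banded unit-cost global alignment of the prefixes of two character vectors.
# Returns the operation string from the start: M match, X mismatch,
# D gap-in-b (consumes a), I gap-in-a (consumes b).
banded_align_ops <- function(a, b, band = 50L) {
  na <- length(a); nb <- length(b)
  stopifnot(abs(na - nb) <= band)
  K <- 2L * band + 1L
  ks <- seq_len(K)
  D <- matrix(Inf, na + 1L, K)
  j0 <- ks - band - 1L            # j at row i = i + j0
  D[1L, ] <- ifelse(j0 >= 0L & j0 <= nb, j0, Inf)
  for (i in seq_len(na)) {
    j <- i + j0
    valid <- j >= 1L & j <= nb
    sub <- rep(Inf, K)
    sub[valid] <- (a[i] != b[j[valid]]) * 1
    diag_ <- D[i, ] + sub
    up <- c(D[i, -1L], Inf) + 1     # D[i-1, j]
    tmp <- pmin(diag_, up)
    tmp[j == 0L] <- i               # leading deletions column
    tmp[!valid & j != 0L] <- Inf
    row <- cummin(tmp - ks) + ks
    D[i + 1L, ] <- pmin(tmp, row)
  }
  # traceback from (na, nb); within a row, relative index k = j - i + band + 1
  i <- na; j <- nb
  ops <- character(na + nb)
  t <- 0L
  while (i > 0L || j > 0L) {
    k <- j - i + band + 1L
    cur <- D[i + 1L, k]
    if (i > 0L && j > 0L && is.finite(D[i, k]) &&
        cur == D[i, k] + (a[i] != b[j]) * 1) {
      t <- t + 1L; ops[t] <- if (a[i] == b[j]) "M" else "X"
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && k + 1L <= K && is.finite(D[i, k + 1L]) &&
               cur == D[i, k + 1L] + 1) {
      t <- t + 1L; ops[t] <- "D"
      i <- i - 1L
    } else if (j > 0L && k - 1L >= 1L && is.finite(D[i + 1L, k - 1L]) &&
               cur == D[i + 1L, k - 1L] + 1) {
      t <- t + 1L; ops[t] <- "I"
      j <- j - 1L
    } else if (i > 0L) {          # leading-deletion column (j == 0)
      t <- t + 1L; ops[t] <- "D"
      i <- i - 1L
    } else {
      t <- t + 1L; ops[t] <- "I"
      j <- j - 1L
    }
  }
  list(ops = rev(ops[seq_len(t)]), score = D[na + 1L, nb - na + band + 1L])
}

# Extend two inward-reading ends; returns kept-column stats or NULL.
extend_ends <- function(a_str, b_str, seed_len, min_identity, window, band,
                        max_scan, max_extend) {
  if (!has_shared_seed(a_str, b_str, seed_len, max_scan)) return(NULL)
  cap <- max_extend
  L <- min(4096L, cap)
  repeat {
    a <- seq_chars(substr(a_str, 1L, L))
    b <- seq_chars(substr(b_str, 1L, L))
    al <- banded_align_ops(a, b, band)
    ops <- al$ops
    m <- ops == "M"
    n <- length(ops)
    cm <- cumsum(m)
    # trailing-window identity; only defined once window columns exist
    stop_idx <- n
    terminated <- FALSE
    if (n > window) {
      trail <- (cm[(window + 1L):n] - cm[1:(n - window)]) / window
      bad <- which(trail < min_identity / 100)
      if (length(bad)) { stop_idx <- bad[1L] + window; terminated <- TRUE }
    }
    if (!terminated && L < cap) { L <- min(2L * L, cap); next }
    # trim: argmax of matches - lambda * differences, last maximum
    lambda <- min_identity / (100 - min_identity + 1e-9)
    sc <- cm - lambda * (seq_len(n) - cm)
    upto <- seq_len(stop_idx)
    best <- max(sc[upto])
    tstar <- max(which(sc[upto] == best))
    if (best <= 0) return(NULL)
    kept <- ops[seq_len(tstar)]
    matches <- sum(kept == "M")
    mismatches <- sum(kept == "X")
    indels <- sum(kept %in% c("I", "D"))
    identity <- 100 * matches / tstar
    if (identity < min_identity) return(NULL)
    a_len <- sum(kept %in% c("M", "X", "D"))
    b_len <- sum(kept %in% c("M", "X", "I"))
    return(list(columns = tstar, matches = matches, mismatches = mismatches,
                indels = indels, percent_identity = identity,
                a_len = a_len, b_len = b_len))
  }
}

has_shared_seed <- function(a_str, b_str, seed_len, max_scan) {
  wa <- substr(a_str, 1L, max_scan)
  wb <- substr(b_str, 1L, max_scan)
  if (nchar(wa) < seed_len || nchar(wb) < seed_len) return(FALSE)
  ka <- substring(wa, 1:(nchar(wa) - seed_len + 1L), seed_len:nchar(wa))
  kb <- substring(wb, 1:(nchar(wb) - seed_len + 1L), seed_len:nchar(wb))
  any(ka %in% kb)
}

#' Detect terminal inverted repeats on a linear replicon
#'
#' Seed-and-extend comparison of the left end with the reverse complement of
#' the right end (see the algorithm sketch in the source header). Defaults
#' are tuned so that a near-identical multi-kilobase TIR is recovered whole
#' while unrelated ends terminate within one window.
#'
#' @param rep A linear \code{replicon}.
#' @param seed_len Exact seed length in bases (default 100, minimum 8).
#' @param min_identity Percent identity threshold for termination/trim
#'   (default 95).
#' @param window Trailing window in aligned columns (default 1000).
#' @param band Alignment band half-width (default 50).
#' @param max_scan Bases from each end searched for the seed (default 10000).
#' @param max_extend Cap on the extension length (default half the replicon).
#' @return A \code{tir_report} (list with \code{replicon_id},
#'   \code{left_interval}, \code{right_interval}, \code{length} in aligned
#'   columns, \code{percent_identity}, \code{matches}, \code{mismatches},
#'   \code{indels}) or \code{NULL} when no TIR is found.
#' @export
find_tir <- function(rep, seed_len = 100L, min_identity = 95, window = 1000L,
                     band = 50L, max_scan = 10000L, max_extend = NULL) {
  stopifnot(inherits(rep, "replicon"), seed_len >= 8L)
  if (rep$topology == "circular")
    stop("TIRs are defined for linear replicons", call. = FALSE)
  len <- rep$length
  if (is.null(max_extend)) max_extend <- floor(len / 2)
  a_str <- rep$sequence
  b_str <- revcomp(rep$sequence)
  res <- extend_ends(a_str, b_str, seed_len, min_identity, window, band,
                     max_scan, max_extend)
  if (is.null(res)) return(NULL)
  structure(list(replicon_id = rep$id,
                 left_interval = c(1L, res$a_len),
                 right_interval = c(len - res$b_len + 1L, len),
                 length = res$columns,
                 percent_identity = res$percent_identity,
                 matches = res$matches, mismatches = res$mismatches,
                 indels = res$indels),
            class = "tir_report")
}

#' @export
print.tir_report <- function(x, ...) {
  cat(sprintf("<tir_report> %s: %d cols, %.2f%% identity, left %d..%d, right %d..%d\n",
              x$replicon_id, x$length, x$percent_identity,
              x$left_interval[1], x$left_interval[2],
              x$right_interval[1], x$right_interval[2]))
  invisible(x)
}

#' Shared terminal homology between two replicons
#'
#' Compares one end of each linear replicon, both read inward (right ends are
#' reverse complemented first), with the same seed-and-extend machinery as
#' \code{\link{find_tir}}.
#'
#' @param rep_a,rep_b Linear \code{replicon}s.
#' @param end_a,end_b \code{"left"} or \code{"right"}.
#' @inheritParams find_tir
#' @return An \code{end_homology_report} (adds \code{interval_a},
#'   \code{interval_b} on the forward strand of each replicon) or
#'   \code{NULL}.
#' @export
end_homology <- function(rep_a, end_a = c("left", "right"),
                         rep_b, end_b = c("left", "right"),
                         seed_len = 100L, min_identity = 95, window = 1000L,
                         band = 50L, max_scan = 10000L, max_extend = NULL) {
  end_a <- match.arg(end_a); end_b <- match.arg(end_b)
  stopifnot(inherits(rep_a, "replicon"), inherits(rep_b, "replicon"))
  if (rep_a$topology == "circular" || rep_b$topology == "circular")
    stop("end homology is defined for linear replicons", call. = FALSE)
  if (is.null(max_extend))
    max_extend <- floor(min(rep_a$length, rep_b$length) / 2)
  inward <- function(r, end) if (end == "left") r$sequence else revcomp(r$sequence)
  res <- extend_ends(inward(rep_a, end_a), inward(rep_b, end_b),
                     seed_len, min_identity, window, band, max_scan, max_extend)
  if (is.null(res)) return(NULL)
  interval <- function(r, end, used)
    if (end == "left") c(1L, used) else c(r$length - used + 1L, r$length)
  structure(list(replicon_a = rep_a$id, replicon_b = rep_b$id,
                 end_a = end_a, end_b = end_b,
                 interval_a = interval(rep_a, end_a, res$a_len),
                 interval_b = interval(rep_b, end_b, res$b_len),
                 length = res$columns,
                 percent_identity = res$percent_identity,
                 matches = res$matches, mismatches = res$mismatches,
                 indels = res$indels),
            class = "end_homology_report")
}

#' Scan a replicon for a motif with mismatches
#'
#' Both strands are scanned (Hamming distance, no indels). A palindromic
#' motif (its own reverse complement, like typical parS sites) yields
#' identical forward and reverse hit sets, so each site is reported once on
#' the forward strand with \code{palindromic = TRUE}.
#'
#' @param rep A \code{replicon}.
#' @param motif DNA string over \code{A,C,G,T}.
#' @param max_mismatches Maximum Hamming distance (default 0).
#' @return A \code{motif_hits} object: list with \code{motif},
#'   \code{replicon_id}, \code{palindromic} and \code{hits} (data frame:
#'   position, strand, mismatches). Positions are the 1-based start of the
#'   match on the forward strand.
#' @export
find_motif <- function(rep, motif, max_mismatches = 0L) {
  stopifnot(inherits(rep, "replicon"))
  assert_dna(motif, "motif")
  subject <- Biostrings::DNAString(rep$sequence)
  palindromic <- identical(motif, revcomp(motif))
  scan <- function(pat, strand) {
    if (nchar(pat) > rep$length) return(NULL)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  max.mismatch = max_mismatches)
    if (!length(m)) return(NULL)
    pos <- BiocGenerics::start(m)
    mm <- vapply(seq_along(m), function(i) {
      sum(seq_chars(as.character(m[[i]])) != seq_chars(pat))
    }, integer(1))
    data.frame(position = pos, strand = strand, mismatches = mm)
  }
  hits <- scan(motif, "+")
  if (!palindromic) hits <- rbind(hits, scan(revcomp(motif), "-"))
  if (is.null(hits)) hits <- data.frame(position = integer(),
                                        strand = character(),
                                        mismatches = integer())
  hits <- hits[order(hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(motif = motif, replicon_id = rep$id,
                 palindromic = palindromic, hits = hits),
            class = "motif_hits")
}

#' Exact k-mer dot plot between two sequences
#'
#' Reports every pair of positions sharing an exact k-mer, forward and
#' reverse complement. When the number of points exceeds \code{max_points}
#' the set is thinned deterministically (every n-th point in sorted order)
#' and the original count is kept.
#'
#' @param seq_a,seq_b DNA strings (or \code{replicon}s).
#' @param k Word size, >= 8 (default 12).
#' @param max_points Point cap (default 100000).
#' @return A \code{dot_plot} object: list with ids, \code{k},
#'   \code{points} (data frame: pos_a, pos_b, strand) and \code{n_total}.
#' @export
dotplot_kmers <- function(seq_a, seq_b, k = 12L, max_points = 100000L) {
  id_a <- if (inherits(seq_a, "replicon")) seq_a$id else "seq_a"
  id_b <- if (inherits(seq_b, "replicon")) seq_b$id else "seq_b"
  if (inherits(seq_a, "replicon")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "replicon")) seq_b <- seq_b$sequence
  stopifnot(k >= 8L)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  ka <- kmers(seq_a)
  match_points <- function(kb, strand, nb) {
    common <- intersect(ka, kb)
    common <- common[!grepl("N", common, fixed = TRUE)]
    if (!length(common)) return(NULL)
    ia <- split(seq_along(ka), ka)[common]
    ib <- split(seq_along(kb), kb)[common]
    pts <- do.call(rbind, lapply(seq_along(common), function(i)
      expand.grid(pos_a = ia[[i]], pos_b = ib[[i]])))
    if (strand == "-") pts$pos_b <- nb - k + 2L - pts$pos_b  # map back to forward coords
    pts$strand <- strand
    pts
  }
  nb <- nchar(seq_b)
  pts <- rbind(match_points(kmers(seq_b), "+", nb),
               match_points(kmers(revcomp(seq_b)), "-", nb))
  if (is.null(pts)) pts <- data.frame(pos_a = integer(), pos_b = integer(),
                                      strand = character())
  pts <- pts[order(pts$strand, pts$pos_a, pts$pos_b), , drop = FALSE]
  n_total <- nrow(pts)
  if (n_total > max_points)
    pts <- pts[seq(1L, n_total, length.out = max_points), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(seq_a_id = id_a, seq_b_id = id_b, k = k,
                 points = pts, n_total = n_total),
            class = "dot_plot")
}
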