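# Codon usage: per-replicon 64-codon count/percentage tables, tie-aware
# Spearman rank correlation between replicons, and RSCU. Codons are read in
# frame from strand-corrected CDS; CDS flagged partial or whose length is not
# a multiple of 3 are excluded (frameshifted annotations would otherwise
# pollute the table) and their number is reported. Stop codons are counted by
# default; an exclude toggle is provided because published percentage plots
# do not always state the convention.

#' Codon usage table for a replicon
#'
#' @param rep A \code{replicon} with parsed CDS.
#' @param include_stops Count the three stop codons (default TRUE).
#' @return Object of class \code{codon_usage}: list with \code{replicon_id},
#'   \code{counts} (named 64-vector), \code{percentages}, \code{total_codons},
#'   \code{n_cds_used}, \code{n_cds_skipped}, \code{n_ambiguous}. An empty
#'   table (no eligible CDS) has \code{total_codons == 0} and is excluded
#'   from correlations.
#' @export
codon_counts <- function(rep, include_stops = TRUE) {
  stopifnot(inherits(rep, "replicon"))
  codons <- all_codons()
  if (!include_stops) codons <- setdiff(codons, stop_codons())
  counts <- stats::setNames(integer(length(codons)), codons)
  n_used <- 0L; n_skipped <- 0L; n_ambig <- 0L
  if (nrow(rep$cds)) {
    seqs <- cds_sequences(rep)
    eligible <- !rep$cds$partial & nchar(seqs) %% 3L == 0L & nchar(seqs) > 0L
    n_skipped <- sum(!eligible)
    n_used <- sum(eligible)
    if (n_used > 0L) {
      tri <- unlist(lapply(seqs[eligible], function(s) {
        substring(s, seq(1L, nchar(s) - 2L, by = 3L), seq(3L, nchar(s), by = 3L))
      }), use.names = FALSE)
      known <- tri %in% all_codons()
      n_ambig <- sum(!known)  # codons containing N (or other ambiguity)
      tab <- table(factor(tri[known], levels = codons))
      counts <- stats::setNames(as.integer(tab), codons)
    }
  }
  total <- sum(counts)
  pct <- if (total > 0L) 100 * counts / total else counts * 0
  structure(list(replicon_id = rep$id, counts = counts, percentages = pct,
                 total_codons = total, n_cds_used = n_used,
                 n_cds_skipped = n_skipped, n_ambiguous = n_ambig),
            class = "codon_usage")
}

#' Tie-aware Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; ties receive their average
#' rank. Implemented directly from the defining formula.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Coefficient in [-1, 1]; \code{NA} with a warning when either
#'   vector has zero variance.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x)  # average ranks for ties
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    warning("Spearman correlation undefined for a zero-variance vector",
            call. = FALSE)
    return(NA_real_)
  }
  sum(dx * dy) / (sx * sy)
}

#' Pairwise Spearman correlation of codon-usage tables
#'
#' Correlates the 64-entry percentage vectors (so replicon size does not
#' dominate) in a fixed codon ordering. Empty tables are excluded with a
#' warning.
#'
#' @param tables List of \code{codon_usage} objects, length >= 2 after
#'   exclusions.
#' @return Symmetric correlation matrix with unit diagonal, labelled by
#'   replicon id.
#' @export
codon_correlation <- function(tables) {
  ok <- vapply(tables, function(t) t$total_codons > 0L, logical(1))
  if (any(!ok))
    warning(sum(!ok), " empty codon table(s) excluded from correlation",
            call. = FALSE)
  tables <- tables[ok]
  stopifnot(length(tables) >= 2L)
  labels <- vapply(tables, `[[`, character(1), "replicon_id")
  codons <- names(tables[[1L]]$percentages)
  mat <- vapply(tables, function(t) t$percentages[codons], numeric(length(codons)))
  rho_matrix(mat, labels)
}

rho_matrix <- function(mat, labels) {
  n <- ncol(mat)
  rho <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    rho[i, j] <- rho[j, i] <- spearman_rho(mat[, i], mat[, j])
  }
  dimnames(rho) <- list(labels, labels)
  rho
}

#' Relative synonymous codon usage
#'
#' Observed count of each codon divided by the mean count of its synonym
#' family under the standard genetic code (stop codons form their own
#' family). Families with zero total get RSCU 0 for all members.
#'
#' @param table A \code{codon_usage}.
#' @return Named numeric vector of RSCU values over the codons in the table.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  counts <- table$counts
  code <- Biostrings::GENETIC_CODE
  # GENETIC_CODE names use T-alphabet codons already
  fam <- code[names(counts)]
  out <- counts * 0
  for (aa in unique(fam)) {
    members <- names(fam)[fam == aa]
    m <- mean(counts[members])
    out[members] <- if (m > 0) counts[members] / m else 0
  }
  out
}
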