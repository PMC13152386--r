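# COG functional-category profiles per replicon and their rank correlation.
# A gene annotated with k category letters contributes once to each of the k
# categories by default (fractional 1/k weighting available); percentages
# are over annotated category assignments, with unannotated genes reported
# but excluded from the denominator.

#' COG-category profile of a replicon
#'
#' Annotation rows are joined to the replicon's CDS by gene id (locus tag).
#' Genes in the table that do not match any CDS are counted and reported,
#' not fatal.
#'
#' @param rep A \code{replicon}.
#' @param annotations Data frame from \code{\link{read_cog_annotations}}.
#' @param multi_letter \code{"full"} (each letter counts 1) or
#'   \code{"fractional"} (each letter counts 1/k).
#' @return Object of class \code{cog_profile}: list with \code{replicon_id},
#'   \code{category_counts}, \code{category_percent},
#'   \code{n_genes_annotated}, \code{n_genes_unannotated},
#'   \code{n_unmatched}.
#' @export
cog_profile <- function(rep, annotations, multi_letter = c("full", "fractional")) {
  stopifnot(inherits(rep, "replicon"))
  multi_letter <- match.arg(multi_letter)
  tags <- rep$cds$locus_tag
  joined <- annotations[annotations$gene_id %in% tags, , drop = FALSE]
  n_unmatched <- sum(!(annotations$gene_id %in% tags))
  # tolerate raw "-" (no category) that has not been through the reader
  joined$cog_letters <- gsub("[^A-Z]", "", joined$cog_letters)
  annotated <- joined[nzchar(joined$cog_letters), , drop = FALSE]
  n_unannot <- sum(!nzchar(joined$cog_letters))
  counts <- numeric(0)
  if (nrow(annotated)) {
    letter_lists <- strsplit(annotated$cog_letters, "", fixed = TRUE)
    w <- if (multi_letter == "full") rep.int(1, length(unlist(letter_lists)))
         else rep.int(1 / lengths(letter_lists), lengths(letter_lists))
    letters_all <- unlist(letter_lists, use.names = FALSE)
    counts <- tapply(w, letters_all, sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts
  structure(list(replicon_id = rep$id,
                 category_counts = counts, category_percent = pct,
                 n_genes_annotated = nrow(annotated),
                 n_genes_unannotated = n_unannot,
                 n_unmatched = n_unmatched),
            class = "cog_profile")
}

#' Unmatched annotation genes for a genome
#'
#' Count of annotation rows whose gene id matches no CDS of any replicon.
#'
#' @param g A \code{genome}.
#' @param annotations Annotation data frame.
#' @return Integer.
#' @export
unmatched_annotations <- function(g, annotations) {
  tags <- unlist(lapply(g$replicons, function(r) r$cds$locus_tag), use.names = FALSE)
  sum(!(annotations$gene_id %in% tags))
}

#' Categories reaching a display threshold
#'
#' @param profiles List of \code{cog_profile}s.
#' @param min_percent Minimum percentage a category must reach in at least
#'   one profile (default 1).
#' @return Alphabetically sorted character vector of category letters.
#' @export
filter_display_categories <- function(profiles, min_percent = 1) {
  stopifnot(min_percent >= 0, min_percent <= 100)
  keep <- unique(unlist(lapply(profiles, function(p) {
    names(p$category_percent)[p$category_percent >= min_percent]
  })))
  sort(keep)
}

#' Pairwise Spearman correlation of COG profiles
#'
#' Profiles are aligned on the union of observed categories (absent
#' categories filled with 0) and correlated over percentage vectors.
#'
#' @param profiles List of \code{cog_profile}s, length >= 2.
#' @param drop_unknown Drop category S (function unknown) before
#'   correlating (default FALSE; the conventional plots keep it).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cog_correlation <- function(profiles, drop_unknown = FALSE) {
  stopifnot(length(profiles) >= 2L)
  universe <- sort(unique(unlist(lapply(profiles, function(p)
    names(p$category_percent)))))
  if (drop_unknown) universe <- setdiff(universe, "S")
  if (length(universe) < 3L)
    stop("fewer than 3 categories observed; correlation not meaningful",
         call. = FALSE)
  labels <- vapply(profiles, `[[`, character(1), "replicon_id")
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(universe)), universe)
    common <- intersect(universe, names(p$category_percent))
    v[common] <- p$category_percent[common]
    if (length(unique(v)) < 3L)
      warning("profile ", p$replicon_id, " has fewer than 3 distinct values",
              call. = FALSE)
    v
  }, numeric(length(universe)))
  rho_matrix(mat, labels)
}
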