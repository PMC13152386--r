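# Taxon-rank gene specificity. A presence/absence matrix (query proteins x
# target genomes) is thresholded from a tabular homology hit table, then each
# protein is scored at the strain, genus and family level by
#
#   score = fA^2 / (fA + fB)          (default)
#   score = fA / (2*fA + fB)          (alternative rendering, behind a flag)
#
# where fA and fB are the frequencies of genomes in groups A and B carrying a
# qualifying homologue. Group A is the focal strain / the focal genus / the
# focal family depending on the level; group B is everything else. A protein
# always counts as present in its own genome.

#' Presence/absence matrix from a homology hit table
#'
#' presence(q, g) is true iff any hit of query q against a protein of genome
#' g passes all thresholds. Coverage is alignment_length / query_length when
#' the query length is available; otherwise the coverage test is skipped with
#' a warning.
#'
#' @param hits Data frame from \code{\link{read_hit_table}}.
#' @param queries Optional character vector fixing the row universe (queries
#'   with no passing hits then appear as all-false rows).
#' @param genomes Optional character vector fixing the column universe.
#' @param evalue_max,min_identity,min_coverage Thresholds; defaults 0.001,
#'   25 (percent identity), 50 (percent query coverage).
#' @return Logical matrix, rows = queries, columns = genomes.
#' @export
presence_from_hits <- function(hits, queries = NULL, genomes = NULL,
                               evalue_max = 0.001, min_identity = 25,
                               min_coverage = 50) {
  if (is.null(queries)) queries <- sort(unique(hits$query_id))
  if (is.null(genomes)) genomes <- sort(unique(hits$genome_id))
  mat <- matrix(FALSE, length(queries), length(genomes),
                dimnames = list(queries, genomes))
  if (!nrow(hits)) {
    warning("no hits: all-false presence matrix", call. = FALSE)
    return(mat)
  }
  pass <- hits$evalue <= evalue_max & hits$percent_identity >= min_identity
  has_qlen <- !is.na(hits$query_length) & hits$query_length > 0
  if (any(!has_qlen))
    warning(sum(!has_qlen), " hits lack query_length; coverage test skipped for them",
            call. = FALSE)
  cov_ok <- rep(TRUE, nrow(hits))
  cov_ok[has_qlen] <- 100 * hits$alignment_length[has_qlen] /
    hits$query_length[has_qlen] >= min_coverage
  pass <- pass & cov_ok
  ph <- hits[pass & hits$query_id %in% queries & hits$genome_id %in% genomes, ]
  mat[cbind(ph$query_id, ph$genome_id)] <- TRUE
  mat
}

#' Taxon-specificity score
#'
#' @param fA,fB Frequencies in [0, 1]; not both zero.
#' @param formula \code{"sq"}: fA^2/(fA+fB) (default); \code{"alt"}:
#'   fA/(2*fA+fB).
#' @return Score in [0, 1]; 1 = unique to group A, 0.5 = ubiquitous.
#' @export
specificity_score <- function(fA, fB, formula = c("sq", "alt")) {
  formula <- match.arg(formula)
  stopifnot(all(fA >= 0 & fA <= 1), all(fB >= 0 & fB <= 1))
  if (any(fA == 0 & fB == 0))
    stop("specificity undefined when fA == fB == 0", call. = FALSE)
  if (formula == "sq") fA^2 / (fA + fB) else fA / (2 * fA + fB)
}

#' Score every protein at one taxon level
#'
#' Level selects the A/B split from the grouping table: \code{strain} (A =
#' the focal genome), \code{genus} (A = all genomes of the focal genus),
#' \code{family} (A = all genomes of the focal family). fA and fB are the
#' fractions of group-A/B genomes carrying the protein; the focal genome
#' always counts as carrying its own proteins.
#'
#' @param presence Logical matrix from \code{\link{presence_from_hits}}.
#' @param grouping Data frame with columns \code{genome_id}, \code{strain},
#'   \code{genus}, \code{family} covering every matrix column.
#' @param level One of \code{"strain"}, \code{"genus"}, \code{"family"}.
#' @param focal_genome Genome id of the focal strain.
#' @param query_replicon Named character vector mapping query protein id to
#'   its source replicon.
#' @param formula Passed to \code{\link{specificity_score}}.
#' @return Data frame of specificity records: \code{protein_id},
#'   \code{replicon_id}, \code{level}, \code{fA}, \code{fB}, \code{score}.
#' @export
score_all <- function(presence, grouping, level = c("strain", "genus", "family"),
                      focal_genome, query_replicon = NULL,
                      formula = c("sq", "alt")) {
  level <- match.arg(level)
  formula <- match.arg(formula)
  genomes <- colnames(presence)
  missing_g <- setdiff(genomes, grouping$genome_id)
  if (length(missing_g))
    stop("genomes without taxon labels: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  gr <- grouping[match(genomes, grouping$genome_id), ]
  focal <- grouping[grouping$genome_id == focal_genome, ]
  if (!nrow(focal)) stop("focal genome not in grouping", call. = FALSE)
  in_A <- switch(level,
                 strain = genomes == focal_genome,
                 genus = gr$genus == focal$genus,
                 family = gr$family == focal$family)
  if (!any(!in_A)) stop("group B is empty at level ", level, call. = FALSE)
  if (!any(in_A)) stop("group A is empty at level ", level, call. = FALSE)
  pres <- presence
  if (focal_genome %in% genomes) pres[, focal_genome] <- TRUE
  fA <- rowMeans(pres[, in_A, drop = FALSE])
  fB <- rowMeans(pres[, !in_A, drop = FALSE])
  data.frame(protein_id = rownames(pres),
             replicon_id = if (is.null(query_replicon)) NA_character_
                           else unname(query_replicon[rownames(pres)]),
             level = level, fA = fA, fB = fB,
             score = specificity_score(fA, fB, formula),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-replicon specificity summaries
#'
#' Median and quartiles (linear-interpolation, quantile type 7) of the
#' scores, grouped by (replicon, level). Empty groups are skipped.
#'
#' @param records Data frame from \code{\link{score_all}} (possibly several
#'   levels bound together).
#' @return Data frame: \code{replicon_id}, \code{level}, \code{median},
#'   \code{q1}, \code{q3}, \code{n}.
#' @export
summarize_by_replicon <- function(records) {
  stopifnot(all(c("replicon_id", "level", "score") %in% names(records)))
  records <- records[!is.na(records$replicon_id), , drop = FALSE]
  groups <- unique(records[, c("replicon_id", "level")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    s <- records$score[records$replicon_id == groups$replicon_id[i] &
                       records$level == groups$level[i]]
    s <- s[!is.na(s)]
    if (!length(s)) return(NULL)
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(replicon_id = groups$replicon_id[i], level = groups$level[i],
               median = q[2L], q1 = q[1L], q3 = q[3L], n = length(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
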