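# Pipeline orchestration: run every analysis stage over one genome in
# dependency order, assemble a per-replicon summary with a class label for
# each replicon, and degrade gracefully when optional inputs (annotations,
# hit table, grouping, core genes) are missing — the dependent axes are
# reported as not measured and classification falls back with its rationale.

#' Default pipeline configuration
#'
#' @param window_size,step GC-skew window parameters (bases).
#' @param include_stops Count stop codons in codon usage.
#' @param multi_letter COG multi-letter weighting, \code{"full"} or
#'   \code{"fractional"}.
#' @param evalue_max,min_identity,min_coverage Homology presence thresholds.
#' @param formula Specificity formula (\code{"sq"} or \code{"alt"}).
#' @param tir_seed_len,tir_min_identity,tir_window,tir_band,tir_max_scan
#'   TIR detection parameters.
#' @param thresholds Classification thresholds
#'   (\code{\link{classification_thresholds}}).
#' @param run_specificity,run_tir Stage toggles.
#' @return Named list.
#' @export
default_config <- function(window_size = 10000L, step = 5000L,
                           include_stops = TRUE,
                           multi_letter = "full",
                           evalue_max = 0.001, min_identity = 25,
                           min_coverage = 50, formula = "sq",
                           tir_seed_len = 100L, tir_min_identity = 95,
                           tir_window = 1000L, tir_band = 50L,
                           tir_max_scan = 10000L,
                           thresholds = classification_thresholds(),
                           run_specificity = TRUE, run_tir = TRUE) {
  as.list(environment())
}

#' Run the full replicon-characterisation pipeline
#'
#' Stages in dependency order: composition -> codon usage -> COG profiles ->
#' TIR detection -> marker survey -> specificity -> classification.
#'
#' @param g A \code{genome}.
#' @param annotations Optional annotation data frame
#'   (\code{\link{read_cog_annotations}} schema).
#' @param hits Optional hit table (\code{\link{read_hit_table}} schema).
#' @param grouping Optional taxon grouping data frame; required for
#'   specificity.
#' @param core_genes Optional core-gene data frame (gene_id, replicon_id).
#' @param query_replicon Optional named vector protein id -> replicon; when
#'   NULL it is derived from the genome's locus tags.
#' @param focal_genome Focal genome id for specificity (defaults to the
#'   grouping's first genome).
#' @param config See \code{\link{default_config}}.
#' @param out_dir Optional output directory for stage TSVs.
#' @return A \code{report_bundle}: list with \code{summary} (per-replicon
#'   data frame), \code{stages} (all stage objects) and \code{log}
#'   (character vector).
#' @export
run_all <- function(g, annotations = NULL, hits = NULL, grouping = NULL,
                    core_genes = NULL, query_replicon = NULL,
                    focal_genome = NULL, config = default_config(),
                    out_dir = NULL) {
  stopifnot(inherits(g, "genome"))
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  ids <- names(g$replicons)
  chr <- chromosome_id(g)

  comp <- composition_summary(g)
  note("composition: ", nrow(comp), " replicons")

  profiles <- lapply(g$replicons, function(r)
    sliding_windows(r, config$window_size, config$step))

  tables <- lapply(g$replicons, codon_counts,
                   include_stops = config$include_stops)
  nonempty <- vapply(tables, function(t) t$total_codons > 0L, logical(1))
  codon_rho <- if (sum(nonempty) >= 2L) codon_correlation(tables[nonempty]) else NULL
  note("codon usage: ", sum(nonempty), " non-empty tables")

  cogs <- NULL; cog_rho <- NULL
  if (!is.null(annotations)) {
    cogs <- lapply(g$replicons, cog_profile, annotations = annotations,
                   multi_letter = config$multi_letter)
    with_counts <- vapply(cogs, function(p) length(p$category_counts) >= 3L,
                          logical(1))
    if (sum(with_counts) >= 2L) cog_rho <- cog_correlation(cogs[with_counts])
    note("COG profiles: ", sum(with_counts), " usable")
  } else note("COG profiles: not measured (no annotations)")

  tirs <- NULL
  if (isTRUE(config$run_tir)) {
    tirs <- lapply(g$replicons, function(r) {
      if (r$topology == "circular") return(NULL)
      find_tir(r, seed_len = config$tir_seed_len,
               min_identity = config$tir_min_identity,
               window = config$tir_window, band = config$tir_band,
               max_scan = config$tir_max_scan)
    })
    note("TIR: ", sum(!vapply(tirs, is.null, logical(1))), " replicons with TIRs")
  }

  markers <- lapply(g$replicons, survey_markers,
                    cluster_span = config$thresholds$cluster_span)

  spec_summary <- NULL
  if (isTRUE(config$run_specificity) && !is.null(hits) && !is.null(grouping)) {
    if (is.null(focal_genome)) focal_genome <- grouping$genome_id[1L]
    if (is.null(query_replicon)) {
      query_replicon <- stats::setNames(
        rep(ids, vapply(g$replicons, function(r) nrow(r$cds), integer(1))),
        unlist(lapply(g$replicons, function(r) r$cds$locus_tag), use.names = FALSE))
    }
    pres <- presence_from_hits(hits,
                               queries = names(query_replicon),
                               genomes = grouping$genome_id,
                               evalue_max = config$evalue_max,
                               min_identity = config$min_identity,
                               min_coverage = config$min_coverage)
    recs <- do.call(rbind, lapply(c("strain", "genus", "family"), function(lv)
      score_all(pres, grouping, lv, focal_genome, query_replicon,
                formula = config$formula)))
    spec_summary <- summarize_by_replicon(recs)
    note("specificity: ", nrow(spec_summary), " replicon/level summaries")
  } else note("specificity: not measured")

  analyses <- list(composition = comp, codon_rho = codon_rho,
                   cog_rho = cog_rho, markers = markers,
                   specificity = spec_summary, profiles = profiles,
                   codon_tables = tables, cog_profiles = cogs, tirs = tirs)

  fvs <- lapply(ids, function(id)
    build_feature_vector(g, id, analyses, core_gene_table = core_genes))
  names(fvs) <- ids
  classes <- lapply(fvs, classify, thresholds = config$thresholds)

  fmt <- function(x, digits = 3) ifelse(is.na(x), "not measured",
                                        formatC(x, digits = digits, format = "f"))
  summary <- data.frame(
    replicon_id = ids,
    length = comp$length[match(ids, comp$replicon_id)],
    topology = comp$topology[match(ids, comp$replicon_id)],
    gc_molpct = round(comp$gc_molpct[match(ids, comp$replicon_id)], 1),
    codon_rho = vapply(fvs, function(f) f$codon_rho, numeric(1)),
    cog_rho = vapply(fvs, function(f) f$cog_rho, numeric(1)),
    tir = vapply(ids, function(id) {
      t <- if (is.null(tirs)) NULL else tirs[[id]]
      if (is.null(t)) "none" else sprintf("%d cols @ %.2f%%", t$length,
                                          t$percent_identity)
    }, character(1)),
    origin_call = vapply(markers, `[[`, character(1), "origin_call"),
    genus_specificity_median = vapply(ids, function(id) {
      if (is.null(spec_summary)) return(NA_real_)
      v <- spec_summary$median[spec_summary$replicon_id == id &
                               spec_summary$level == "genus"]
      if (length(v)) v[1L] else NA_real_
    }, numeric(1)),
    class = vapply(classes, `[[`, character(1), "label"),
    row.names = NULL)

  bundle <- structure(list(summary = summary, stages = analyses,
                           feature_vectors = fvs, classes = classes,
                           log = log, config = config),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$summary)
  invisible(x)
}

#' Write a report bundle's stage TSVs
#'
#' @param bundle A \code{report_bundle}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$summary, file.path(out_dir, "summary.tsv"))
  long <- do.call(rbind, lapply(bundle$stages$codon_tables, function(t) {
    if (t$total_codons == 0L) return(NULL)
    data.frame(replicon_id = t$replicon_id, codon = names(t$counts),
               count = unname(t$counts), percent = unname(t$percentages))
  }))
  if (!is.null(long)) write_tsv(long, file.path(out_dir, "codon_usage.tsv"))
  if (!is.null(bundle$stages$codon_rho))
    utils::write.table(bundle$stages$codon_rho,
                       file.path(out_dir, "codon_rho.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(bundle$stages$cog_rho))
    utils::write.table(bundle$stages$cog_rho, file.path(out_dir, "cog_rho.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(bundle$stages$specificity))
    write_tsv(bundle$stages$specificity, file.path(out_dir, "specificity.tsv"))
  skews <- do.call(rbind, lapply(bundle$stages$profiles, function(p) {
    data.frame(replicon_id = p$replicon_id, center = p$windows$center,
               gc_percent = 100 * p$windows$gc_fraction,
               skew = p$windows$skew, cumulative_skew = p$cumulative)
  }))
  write_tsv(skews, file.path(out_dir, "gc_skew.tsv"))
  rationale <- unlist(lapply(bundle$classes, function(cl)
    sprintf("%s\t%s\t%s", cl$replicon_id, cl$label,
            paste(cl$rationale, collapse = "; "))))
  writeLines(c("replicon_id\tclass\trationale", rationale),
             file.path(out_dir, "classification.tsv"))
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Size arithmetic over a replicon size table
#'
#' @param sizes Named numeric vector of replicon sizes in bp (the largest is
#'   taken as the chromosome).
#' @return List with \code{total} and \code{table}: per replicon, percent of
#'   total (one decimal), ratio to the chromosome and ratio to the
#'   next-largest replicon (both to two decimals; ratio to next also rounded
#'   to the nearest integer). Ratios are omitted with fewer than two
#'   replicons.
#' @export
check_sizes <- function(sizes) {
  stopifnot(is.numeric(sizes), length(sizes) >= 1L, !is.null(names(sizes)))
  total <- sum(sizes)
  ord <- order(sizes, decreasing = TRUE)
  s <- sizes[ord]
  tab <- data.frame(replicon = names(s), size_bp = unname(s),
                    percent_of_total = round(100 * unname(s) / total, 1),
                    row.names = NULL)
  if (length(s) >= 2L) {
    tab$ratio_to_chromosome <- round(unname(s) / s[[1L]], 2)
    nxt <- c(unname(s)[-1L], NA)
    tab$ratio_to_next <- round(unname(s) / nxt, 2)
    tab$ratio_to_next_int <- round(unname(s) / nxt)
  }
  list(total = total, table = tab)
}
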