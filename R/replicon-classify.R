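# Replication-marker survey and the replicon classification rubric.
#
# The survey matches CDS annotation text (locus tag / product) against a
# configurable vocabulary for the ten canonical markers: dnaA/dnaN
# (chromosomal origin), rep1/rep2 (plasmid iteron + helicase), parA/parB
# (partitioning), gyrA/gyrB, tap/tpg (linear-end patching). The origin call
# follows the marker co-occurrence rules; classification then combines size,
# core genes, composition similarity to the chromosome and the origin call
# into one of five labels: chromosome, secondary chromosome, chromid,
# megaplasmid, plasmid.

#' Default marker vocabulary
#'
#' Named list of case-insensitive regular expressions matched against each
#' CDS's locus tag and product text.
#'
#' @return Named list of patterns.
#' @export
default_marker_vocabulary <- function() {
  list(
    dnaA = "\\bdnaA\\b|chromosomal replication initiat",
    dnaN = "\\bdnaN\\b|DNA polymerase III.*beta|beta sliding clamp",
    parA = "\\bparA\\b|partition(ing)? (protein )?ParA|ParA family ATPase",
    parB = "\\bparB\\b|partition(ing)? (protein )?ParB|ParB family",
    gyrA = "\\bgyrA\\b|gyrase.*subunit A",
    gyrB = "\\bgyrB\\b|gyrase.*subunit B",
    rep1 = "\\brep1\\b|plasmid replication iteron",
    rep2 = "\\brep2\\b|plasmid replicative (DNA )?helicase",
    tap  = "\\btap\\b|telomere-associated protein",
    tpg  = "\\btpg\\b|terminal protein"
  )
}

#' Survey replication markers on a replicon
#'
#' @param rep A \code{replicon} with annotated CDS (product text).
#' @param vocabulary Named list of regex patterns (see
#'   \code{\link{default_marker_vocabulary}}).
#' @param cluster_span Maximum separation, in gene ranks along the replicon,
#'   for two markers to count as co-located (default 5).
#' @return A \code{marker_survey}: list with \code{replicon_id},
#'   \code{markers} (named list of data frames locus_tag/position) and
#'   \code{origin_call} in \code{chromosomal}, \code{plasmid},
#'   \code{incomplete-chromosomal}, \code{none}.
#' @export
survey_markers <- function(rep, vocabulary = default_marker_vocabulary(),
                           cluster_span = 5L) {
  stopifnot(inherits(rep, "replicon"))
  if (!nrow(rep$cds)) {
    warning("replicon ", rep$id, " has no CDS; origin call is none", call. = FALSE)
    return(structure(list(replicon_id = rep$id,
                          markers = stats::setNames(vector("list", length(vocabulary)),
                                                    names(vocabulary)),
                          origin_call = "none"),
                     class = "marker_survey"))
  }
  cds <- rep$cds[order(rep$cds$start), , drop = FALSE]
  text <- paste(ifelse(is.na(cds$locus_tag), "", cds$locus_tag),
                ifelse(is.na(cds$product), "", cds$product))
  markers <- lapply(vocabulary, function(pat) {
    idx <- grep(pat, text, ignore.case = TRUE, perl = TRUE)
    if (!length(idx)) return(NULL)
    data.frame(locus_tag = cds$locus_tag[idx], position = cds$start[idx],
               rank = idx, stringsAsFactors = FALSE)
  })
  ranks <- function(name) if (is.null(markers[[name]])) integer() else markers[[name]]$rank
  close_pair <- function(x, y, span) {
    length(x) && length(y) && min(abs(outer(x, y, "-"))) <= span
  }
  origin_call <-
    if (close_pair(ranks("dnaA"), ranks("dnaN"), cluster_span)) "chromosomal"
    else if (close_pair(ranks("rep1"), ranks("rep2"), cluster_span)) "plasmid"
    else if ((length(ranks("dnaN")) || length(ranks("parA"))) &&
             !length(ranks("dnaA"))) "incomplete-chromosomal"
    else "none"
  structure(list(replicon_id = rep$id, markers = markers,
                 origin_call = origin_call),
            class = "marker_survey")
}

#' Classification thresholds
#'
#' @param megaplasmid_min Minimum size in bp for a non-chromosomal replicon
#'   to be more than a plasmid (default 350000, the conventional bound).
#' @param gc_tol Maximum G+C difference from the chromosome, in mol
#'   percentage points, still counting as chromosome-like (default 1.0).
#' @param rho_min Minimum Spearman codon-usage correlation with the
#'   chromosome for chromosome-like composition (default 0.9).
#' @param cluster_span Marker co-location span in genes (default 5).
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(megaplasmid_min = 350000,
                                      gc_tol = 1.0, rho_min = 0.9,
                                      cluster_span = 5L) {
  list(megaplasmid_min = megaplasmid_min, gc_tol = gc_tol,
       rho_min = rho_min, cluster_span = cluster_span)
}

#' Feature vector for one replicon
#'
#' Collects the measured classification axes from completed analyses. The
#' chromosome is the genome's largest replicon; its own vector has size
#' ratio 1, delta_gc 0 and unit correlations.
#'
#' @param g A \code{genome}.
#' @param replicon_id Replicon to describe.
#' @param analyses List with elements \code{composition} (from
#'   \code{\link{composition_summary}}), \code{codon_rho} and \code{cog_rho}
#'   (correlation matrices; may be NULL), \code{markers} (named list of
#'   \code{marker_survey}s) and optionally \code{specificity} (summary data
#'   frame) — as produced by \code{\link{run_all}}.
#' @param core_gene_table Optional data frame with columns \code{gene_id},
#'   \code{replicon_id} listing core genes (e.g. single-copy orthologues)
#'   and where they reside.
#' @param genus_median_tol Absolute difference in genus-level median
#'   specificity from the chromosome below which the profile is called
#'   chromosome-like (default 0.25).
#' @return A \code{feature_vector} list.
#' @export
build_feature_vector <- function(g, replicon_id, analyses,
                                 core_gene_table = NULL,
                                 genus_median_tol = 0.25) {
  stopifnot(inherits(g, "genome"), replicon_id %in% names(g$replicons))
  comp <- analyses$composition
  if (is.null(comp)) stop("missing upstream result: composition", call. = FALSE)
  if (is.null(analyses$markers)) stop("missing upstream result: markers", call. = FALSE)
  chr <- chromosome_id(g)
  row <- comp[comp$replicon_id == replicon_id, ]
  chr_row <- comp[comp$replicon_id == chr, ]
  get_rho <- function(m) {
    if (is.null(m) || !(replicon_id %in% rownames(m)) || !(chr %in% rownames(m)))
      return(NA_real_)
    m[replicon_id, chr]
  }
  has_core <- NA
  if (!is.null(core_gene_table) && nrow(core_gene_table)) {
    on_this <- core_gene_table$gene_id[core_gene_table$replicon_id == replicon_id]
    elsewhere <- core_gene_table$gene_id[core_gene_table$replicon_id != replicon_id]
    has_core <- length(setdiff(on_this, elsewhere)) >= 1L
  }
  genus_profile <- NA_character_
  spec <- analyses$specificity
  if (!is.null(spec)) {
    gm <- function(id) {
      v <- spec$median[spec$replicon_id == id & spec$level == "genus"]
      if (length(v)) v[1L] else NA_real_
    }
    mine <- gm(replicon_id); chrm <- gm(chr)
    if (!is.na(mine) && !is.na(chrm))
      genus_profile <- if (abs(mine - chrm) <= genus_median_tol)
        "chromosome-like" else "plasmid-like"
  }
  structure(list(
    replicon_id = replicon_id,
    is_chromosome = replicon_id == chr,
    size_bp = row$length,
    size_ratio_to_chromosome = row$length / chr_row$length,
    delta_gc = abs(row$gc_molpct - chr_row$gc_molpct),
    codon_rho = if (replicon_id == chr) 1 else get_rho(analyses$codon_rho),
    cog_rho = if (replicon_id == chr) 1 else get_rho(analyses$cog_rho),
    has_core_genes = has_core,
    origin_call = analyses$markers[[replicon_id]]$origin_call,
    genus_specific_profile = genus_profile),
    class = "feature_vector")
}

#' Classify a replicon from its feature vector
#'
#' Decision order: (1) the chromosome is the largest replicon; (2) below the
#' megaplasmid bound it is a plasmid; (3) without core genes it is a
#' megaplasmid; (4) core genes + chromosome-like composition + plasmid-type
#' origin make a chromid; (5) core genes + chromosome-like composition with
#' any non-plasmid origin call make a secondary chromosome; (6) otherwise a
#' megaplasmid (with the conflict noted in the rationale).
#'
#' @param fv A \code{feature_vector}.
#' @param thresholds See \code{\link{classification_thresholds}}.
#' @return A \code{replicon_class}: list with \code{label} and
#'   \code{rationale} (character vector of satisfied/violated rubric rows).
#' @export
classify <- function(fv, thresholds = classification_thresholds()) {
  stopifnot(inherits(fv, "feature_vector"))
  th <- thresholds
  rationale <- character()
  add <- function(txt) rationale <<- c(rationale, txt)
  label <- NULL
  if (isTRUE(fv$is_chromosome)) {
    add("largest replicon of the genome")
    label <- "chromosome"
  } else if (fv$size_bp < th$megaplasmid_min) {
    add(sprintf("size %d bp below megaplasmid bound %d bp",
                fv$size_bp, as.integer(th$megaplasmid_min)))
    label <- "plasmid"
  } else {
    add(sprintf("size %d bp at or above megaplasmid bound", fv$size_bp))
    comp_like <- !is.na(fv$delta_gc) && fv$delta_gc <= th$gc_tol &&
      !is.na(fv$codon_rho) && fv$codon_rho >= th$rho_min
    add(sprintf("composition %s chromosome-like (delta G+C %.2f mol%%, codon rho %s)",
                if (comp_like) "is" else "is not", fv$delta_gc,
                if (is.na(fv$codon_rho)) "not measured"
                else sprintf("%.3f", fv$codon_rho)))
    if (!isTRUE(fv$has_core_genes)) {
      add(if (is.na(fv$has_core_genes)) "core genes not measured"
          else "no core genes unique to this replicon")
      label <- "megaplasmid"
    } else {
      add("carries core genes absent from all other replicons")
      if (comp_like && identical(fv$origin_call, "plasmid")) {
        add("plasmid-type replication system (rep1/rep2)")
        label <- "chromid"
      } else if (comp_like) {
        add(sprintf("origin call '%s' (no plasmid-type replicon found)",
                    fv$origin_call))
        label <- "secondary chromosome"
      } else {
        add("core genes present but composition differs from the chromosome; conflicting evidence")
        label <- "megaplasmid"
      }
    }
  }
  structure(list(label = label, rationale = rationale,
                 replicon_id = fv$replicon_id, thresholds = th),
            class = "replicon_class")
}

#' @export
print.replicon_class <- function(x, ...) {
  cat(sprintf("<replicon_class> %s: %s\n", x$replicon_id, x$label))
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}
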