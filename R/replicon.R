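# Domain containers. A Replicon is one DNA molecule with its CDS features; a
# Genome is a named set of replicons plus taxon labels. Both are lightweight
# S3 lists so that every downstream module consumes the same objects
# regardless of whether they came from a GenBank file or the simulator.

#' Construct a replicon
#'
#' @param id Replicon identifier (e.g. an accession).
#' @param sequence DNA string over \code{A,C,G,T,N}.
#' @param topology One of \code{"linear"}, \code{"circular"}, \code{"unknown"}.
#' @param cds A data frame of CDS features with columns \code{locus_tag},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{partial} (logical) and optionally \code{product} and
#'   \code{translation}. Coordinates are 1-based inclusive on the forward
#'   strand.
#' @return An object of class \code{replicon}.
#' @export
replicon <- function(id, sequence, topology = c("linear", "circular", "unknown"),
                     cds = empty_cds()) {
  topology <- match.arg(topology)
  assert_dna(sequence, paste0("sequence of ", id))
  cds <- normalize_cds(cds)
  len <- nchar(sequence)
  if (nrow(cds)) {
    bad <- cds$start < 1L | cds$end > len | cds$start > cds$end
    if (topology == "circular") bad <- cds$start < 1L | cds$start > len | cds$end > 2L * len
    if (any(bad))
      stop("CDS outside [1, ", len, "] on replicon ", id, ": ",
           paste(cds$locus_tag[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 length = len, cds = cds),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s, %d CDS\n",
              x$id, format(x$length, big.mark = ","), x$topology, nrow(x$cds)))
  invisible(x)
}

empty_cds <- function() {
  data.frame(locus_tag = character(), start = integer(), end = integer(),
             strand = character(), partial = logical(),
             product = character(), translation = character(),
             stringsAsFactors = FALSE)
}

normalize_cds <- function(cds) {
  if (is.null(cds) || !nrow(cds)) return(empty_cds())
  for (col in c("product", "translation"))
    if (is.null(cds[[col]])) cds[[col]] <- NA_character_
  if (is.null(cds$partial)) cds$partial <- FALSE
  stopifnot(all(c("locus_tag", "start", "end", "strand") %in% names(cds)))
  stopifnot(all(cds$strand %in% c("+", "-")))
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  rownames(cds) <- NULL
  cds[, names(empty_cds())]
}

#' Strand-corrected CDS nucleotide sequences
#'
#' Extracts the 5'->3' coding sequence of every CDS feature; minus-strand
#' features are reverse complemented. Circular replicons may carry features
#' that wrap the end-start junction (end > length).
#'
#' @param rep A \code{replicon}.
#' @return Character vector, one sequence per CDS row.
#' @export
cds_sequences <- function(rep) {
  stopifnot(inherits(rep, "replicon"))
  if (!nrow(rep$cds)) return(character())
  seq2 <- rep$sequence
  if (rep$topology == "circular") seq2 <- paste0(seq2, rep$sequence)
  out <- substring(seq2, rep$cds$start, rep$cds$end)
  neg <- rep$cds$strand == "-"
  out[neg] <- vapply(out[neg], revcomp, character(1), USE.NAMES = FALSE)
  out
}

#' Construct a genome
#'
#' @param genome_id Genome identifier.
#' @param replicons List of \code{replicon} objects with unique ids.
#' @param strain,genus,family Taxon labels.
#' @return An object of class \code{genome}.
#' @export
genome <- function(genome_id, replicons, strain = genome_id,
                   genus = NA_character_, family = NA_character_) {
  stopifnot(length(replicons) >= 1L,
            all(vapply(replicons, inherits, logical(1), "replicon")))
  ids <- vapply(replicons, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("replicon ids must be unique within a genome", call. = FALSE)
  names(replicons) <- ids
  structure(list(genome_id = genome_id, replicons = replicons,
                 strain = strain, genus = genus, family = family),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%d replicons)\n", x$genome_id, length(x$replicons)))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Identify the chromosome of a genome
#'
#' The chromosome is taken to be the largest replicon, the universal rule for
#' bacterial genomes.
#'
#' @param g A \code{genome}.
#' @return The id of the largest replicon.
#' @export
chromosome_id <- function(g) {
  stopifnot(inherits(g, "genome"))
  lens <- vapply(g$replicons, `[[`, integer(1), "length")
  names(which.max(lens))
}

#' Count CDS features on a replicon
#'
#' @param rep A \code{replicon}.
#' @param require_translation Count only CDS carrying a protein translation.
#' @return Integer count.
#' @export
count_cds <- function(rep, require_translation = FALSE) {
  stopifnot(inherits(rep, "replicon"))
  if (!require_translation) return(nrow(rep$cds))
  sum(!is.na(rep$cds$translation) & nzchar(rep$cds$translation))
}
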