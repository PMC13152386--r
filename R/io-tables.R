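# Tabular readers: eggNOG-mapper-style functional annotations, 12/13-column
# tabular homology hits (BLAST/diamond "outfmt 6" dialect, optionally with a
# trailing query-length column), and the taxon-grouping file. Every reader
# accounts for all input rows: kept + rejected + dropped equals the row count.

#' Read a COG-category annotation table
#'
#' Tab-separated, eggNOG-mapper style: a query-id column and a COG-category
#' column holding one or more upper-case letters, or \code{-} for none.
#' Comment lines start with \code{#}; a comment line that itself contains the
#' column names (as eggNOG-mapper emits, e.g. \code{#query ... COG_category})
#' is used as the header.
#'
#' @param path Path to the annotation file.
#' @param category_column Optional column index for headerless files; by
#'   default the column is located by header name (matching
#'   \code{COG_category}/\code{cog}).
#' @param id_column Optional query-id column index for headerless files.
#' @return A data frame with columns \code{gene_id}, \code{cog_letters},
#'   \code{description}; attribute \code{n_dropped} counts duplicate gene ids
#'   dropped (first occurrence kept).
#' @export
read_cog_annotations <- function(path, category_column = NULL, id_column = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- startsWith(lines, "#")
  header <- NULL
  if (any(comments)) {
    cand <- lines[comments]
    hit <- grep("query", cand, ignore.case = TRUE)
    if (length(hit)) header <- strsplit(sub("^#", "", cand[hit[length(hit)]]), "\t")[[1]]
  }
  body <- lines[!comments]
  if (is.null(header) && length(body) && is.null(category_column)) {
    first <- strsplit(body[1L], "\t")[[1]]
    if (any(grepl("cog", first, ignore.case = TRUE))) {
      header <- first
      body <- body[-1L]
    }
  }
  if (is.null(category_column)) {
    if (is.null(header))
      stop("cannot locate the COG category column: no header found; ",
           "pass category_column for headerless files", call. = FALSE)
    hitcol <- grep("^cog([ _-]?category)?$", header, ignore.case = TRUE)
    if (!length(hitcol)) hitcol <- grep("cog", header, ignore.case = TRUE)
    if (!length(hitcol))
      stop("no COG category column in header: ",
           paste(header, collapse = ", "), call. = FALSE)
    category_column <- hitcol[1L]
    idhit <- grep("query", header, ignore.case = TRUE)
    if (length(idhit)) id_column <- idhit[1L]
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  gene_id <- vapply(fields, function(f) f[id_column], character(1))
  letters_raw <- vapply(fields, function(f)
    if (length(f) >= category_column) f[category_column] else NA_character_,
    character(1))
  if (anyNA(letters_raw))
    stop("rows with missing category column in ", path, call. = FALSE)
  cog_letters <- ifelse(letters_raw == "-", "", gsub("[^A-Z]", "", letters_raw))
  out <- data.frame(gene_id = gene_id, cog_letters = cog_letters,
                    description = NA_character_, stringsAsFactors = FALSE)
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene ids dropped (first kept) in ", path,
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(dup)
  out
}

#' Read a 12-column tabular homology hit table
#'
#' Standard tabular search output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore), optionally with a 13th query-length column. Rows whose
#' subject is absent from the mapping are dropped with a counted warning;
#' rows with non-numeric identity/e-value are rejected with a counted
#' warning.
#'
#' @param path Path to the hit table (no header).
#' @param subject_to_genome Named character vector mapping subject id to
#'   genome id.
#' @return Data frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{evalue},
#'   \code{bitscore}, \code{query_length} (NA when absent), \code{genome_id};
#'   attributes \code{n_dropped} (unmapped subjects) and \code{n_rejected}
#'   (malformed rows).
#' @export
read_hit_table <- function(path, subject_to_genome) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_cols <- lengths(fields)
  bad_shape <- n_cols < 12L
  fields <- fields[!bad_shape]
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (length(fields)) {
    pid <- suppressWarnings(as.numeric(get(3L)))
    alen <- suppressWarnings(as.numeric(get(4L)))
    ev <- suppressWarnings(as.numeric(get(11L)))
    bs <- suppressWarnings(as.numeric(get(12L)))
    qlen <- rep(NA_real_, length(fields))
    has13 <- lengths(fields) >= 13L
    qlen[has13] <- suppressWarnings(as.numeric(vapply(fields[has13], `[[`, character(1), 13L)))
    bad_num <- is.na(pid) | is.na(ev) | is.na(alen) | pid < 0 | pid > 100 | ev < 0
  } else {
    pid <- alen <- ev <- bs <- qlen <- numeric()
    bad_num <- logical()
  }
  n_rejected <- sum(bad_shape) + sum(bad_num)
  keep <- !bad_num
  out <- data.frame(query_id = get(1L)[keep], subject_id = get(2L)[keep],
                    percent_identity = pid[keep], alignment_length = alen[keep],
                    evalue = ev[keep], bitscore = bs[keep],
                    query_length = qlen[keep], stringsAsFactors = FALSE)
  out$genome_id <- unname(subject_to_genome[out$subject_id])
  unmapped <- is.na(out$genome_id)
  n_dropped <- sum(unmapped)
  out <- out[!unmapped, , drop = FALSE]
  if (n_rejected > 0L)
    warning(n_rejected, " malformed hit rows rejected in ", path, call. = FALSE)
  if (n_dropped > 0L)
    warning(n_dropped, " hits with unmapped subjects dropped in ", path, call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a taxon-grouping table
#'
#' Tab-separated with header \code{genome_id, strain, genus, family}.
#'
#' @param path Path to the grouping file.
#' @return Data frame with those four character columns.
#' @export
read_taxon_grouping <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "strain", "genus", "family")
  if (!all(need %in% names(out)))
    stop("grouping file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out[, need]
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
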