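# GenBank flat-file reader/writer. Only the fields the pipeline needs are
# modelled: LOCUS (length + topology), VERSION/ACCESSION (id), CDS features
# with location, /locus_tag, /product, /translation, and ORIGIN. The writer
# emits the same dialect the reader consumes, so simulator output round-trips
# exactly; real multi-record GenBank files (one record per replicon, as
# downloaded from NCBI) parse with the same code path.

#' Read a multi-record GenBank file as a genome
#'
#' One replicon per record. CDS features are extracted with 1-based inclusive
#' coordinates; features whose location carries open-end markers
#' (\code{<}/\code{>}) are flagged partial. Compound (\code{join}/\code{order})
#' locations and CDS outside the sequence bounds are rejected with a warning
#' and the record is kept.
#'
#' @param path Path to a GenBank flat file.
#' @param topology_overrides Optional named character vector mapping record id
#'   to \code{"linear"}/\code{"circular"}; used when the LOCUS line is silent
#'   (which otherwise defaults to linear).
#' @param genome_id,strain,genus,family Labels for the returned genome.
#' @return A \code{genome}.
#' @export
read_genome_genbank <- function(path, topology_overrides = NULL,
                                genome_id = basename(path), strain = genome_id,
                                genus = NA_character_, family = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (!length(ends) || !length(lines)) stop("no records in ", path, call. = FALSE)
  starts <- c(1L, head(ends, -1L) + 1L)
  reps <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:(ends[k] - 1L)]
    reps[[k]] <- parse_genbank_record(block, starts[k], topology_overrides, path)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (!length(reps)) stop("no records in ", path, call. = FALSE)
  genome(genome_id, reps, strain = strain, genus = genus, family = family)
}

parse_genbank_record <- function(block, offset, topology_overrides, path) {
  block <- block[nzchar(trimws(block))]
  if (!length(block)) return(NULL)
  iloc <- grep("^LOCUS", block)
  if (!length(iloc))
    stop("malformed GenBank record (no LOCUS line) near line ", offset,
         " of ", path, call. = FALSE)
  toks <- strsplit(trimws(block[iloc[1L]]), "[[:space:]]+")[[1]]
  locus_name <- toks[2L]
  topology <- if (any(toks == "circular")) "circular"
              else if (any(toks == "linear")) "linear"
              else NA_character_

  id <- locus_name
  iver <- grep("^VERSION", block)
  iacc <- grep("^ACCESSION", block)
  if (length(iver)) {
    v <- strsplit(trimws(block[iver[1L]]), "[[:space:]]+")[[1]]
    if (length(v) >= 2L) id <- v[2L]
  } else if (length(iacc)) {
    v <- strsplit(trimws(block[iacc[1L]]), "[[:space:]]+")[[1]]
    if (length(v) >= 2L) id <- v[2L]
  }
  if (is.na(topology)) {
    topology <- if (!is.null(topology_overrides) && id %in% names(topology_overrides))
      unname(topology_overrides[[id]]) else "linear"
  }

  iori <- grep("^ORIGIN", block)
  if (!length(iori))
    stop("malformed GenBank record ", id, " (no ORIGIN) near line ", offset,
         " of ", path, call. = FALSE)
  seq_lines <- block[(iori[1L] + 1L):length(block)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n_sub <- sum(seq_chars(sequence) %in% c("A", "C", "G", "T", "N") == FALSE)
  if (n_sub > 0L) {
    sequence <- gsub("[^ACGTN]", "N", sequence)
    warning(n_sub, " non-ACGTN bases replaced by N in record ", id, call. = FALSE)
  }

  ifea <- grep("^FEATURES", block)
  cds <- empty_cds()
  if (length(ifea) && iori[1L] > ifea[1L] + 1L) {
    feat_lines <- block[(ifea[1L] + 1L):(iori[1L] - 1L)]
    cds <- parse_cds_features(feat_lines, id)
  }
  # bounds check: reject out-of-range features, keep the record
  len <- nchar(sequence)
  if (nrow(cds)) {
    limit <- if (topology == "circular") 2L * len else len
    bad <- cds$start < 1L | cds$end > limit | cds$start > cds$end |
      (topology != "circular" & cds$end > len)
    if (any(bad)) {
      warning(sum(bad), " CDS outside sequence bounds rejected on record ", id,
              call. = FALSE)
      cds <- cds[!bad, , drop = FALSE]
    }
  }
  replicon(id, sequence, topology, cds)
}

parse_cds_features <- function(feat_lines, record_id) {
  key <- substr(feat_lines, 6L, 20L)
  key_idx <- which(nzchar(trimws(key)))
  if (!length(key_idx)) return(empty_cds())
  keys <- trimws(key[key_idx])
  bounds <- c(key_idx, length(feat_lines) + 1L)
  rows <- list()
  n_rejected <- 0L
  for (i in seq_along(key_idx)) {
    if (keys[i] != "CDS") next
    chunk <- feat_lines[key_idx[i]:(bounds[i + 1L] - 1L)]
    body <- trimws(substr(chunk, 22L, nchar(chunk)))
    body[1L] <- trimws(substr(chunk[1L], 21L, nchar(chunk[1L])))
    # location may continue over lines until the first qualifier
    qual_start <- which(startsWith(body, "/"))
    loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(body)
    loc <- gsub("[[:space:]]", "", paste(body[1:loc_end], collapse = ""))
    parsed <- parse_location(loc)
    if (is.null(parsed)) { n_rejected <- n_rejected + 1L; next }
    quals <- parse_qualifiers(body[seq_along(body) > loc_end])
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = quals[["locus_tag"]] %||% NA_character_,
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      partial = parsed$partial,
      product = quals[["product"]] %||% NA_character_,
      translation = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_rejected > 0L)
    warning(n_rejected, " CDS with unsupported compound locations rejected on record ",
            record_id, call. = FALSE)
  if (!length(rows)) return(empty_cds())
  do.call(rbind, rows)
}

parse_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) return(NULL)
  partial <- grepl("[<>]", loc)
  loc <- gsub("[<>]", "", loc)
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  } else if (grepl("^[0-9]+$", loc)) {
    ab <- rep(as.integer(loc), 2L)
  } else return(NULL)
  list(start = ab[1L], end = ab[2L], strand = strand, partial = partial)
}

parse_qualifiers <- function(body) {
  if (!length(body)) return(list())
  starts <- which(startsWith(body, "/"))
  if (!length(starts)) return(list())
  out <- list()
  bounds <- c(starts, length(body) + 1L)
  for (i in seq_along(starts)) {
    q <- paste(body[starts[i]:(bounds[i + 1L] - 1L)],
               collapse = " ")
    m <- regmatches(q, regexec("^/([A-Za-z_]+)=?(.*)$", q))[[1]]
    if (length(m) < 2L) next
    name <- m[2L]
    val <- gsub('^"|"$', "", trimws(m[3L]))
    if (name == "translation") val <- gsub("[[:space:]]", "", val)
    out[[name]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genome as a multi-record GenBank flat file
#'
#' Emits one record per replicon in the same dialect \code{\link{read_genome_genbank}}
#' consumes, so sequences, topologies, CDS coordinates and strands round-trip
#' exactly.
#'
#' @param g A \code{genome}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rep in g$replicons) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2026",
                       rep$id, rep$length, rep$topology), con)
    writeLines(sprintf("DEFINITION  %s replicon %s.", g$genome_id, rep$id), con)
    writeLines(sprintf("ACCESSION   %s", rep$id), con)
    writeLines(sprintf("VERSION     %s", rep$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rep$length), con)
    if (nrow(rep$cds)) {
      for (j in seq_len(nrow(rep$cds))) {
        f <- rep$cds[j, ]
        loc <- if (f$partial) sprintf("<%d..>%d", f$start, f$end)
               else sprintf("%d..%d", f$start, f$end)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     CDS             %s", loc), con)
        if (!is.na(f$locus_tag))
          writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag), con)
        if (!is.na(f$product))
          writeLines(sprintf('                     /product="%s"', f$product), con)
        if (!is.na(f$translation) && nzchar(f$translation))
          writeLines(wrap_qualifier("translation", f$translation), con)
      }
    }
    writeLines("ORIGIN", con)
    writeLines(format_origin(rep$sequence), con)
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(name, value) {
  text <- sprintf('/%s="%s"', name, value)
  first_width <- 58L
  out <- character()
  while (nchar(text) > first_width) {
    out <- c(out, substr(text, 1L, first_width))
    text <- substr(text, first_width + 1L, nchar(text))
  }
  out <- c(out, text)
  paste0(strrep(" ", 21L), out)
}

format_origin <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(tens, collapse = " ")))
  }, character(1))
}
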