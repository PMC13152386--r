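# Minimal FASTA reader/writer with the package's character policy: sequences
# are upper-cased and anything outside {A,C,G,T,N} becomes N with a counted
# warning. The substitution rule is the reason this is not a
# Biostrings::readDNAStringSet call: that parser rejects non-IUPAC letters
# outright rather than masking them.

#' Read a FASTA file
#'
#' @param path Path to a FASTA text file; mixed case is tolerated.
#' @return Named character vector of upper-cased sequences, in file order,
#'   with attribute \code{n_substituted} giving the number of non-ACGTN
#'   characters replaced by N.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(lines, ">")
  if (length(lines) && !is_header[1L])
    stop("sequence line before any header in ", path, call. = FALSE)
  if (!any(is_header)) {
    out <- character()
    attr(out, "n_substituted") <- 0L
    return(out)
  }
  grp <- cumsum(is_header)
  ids <- sub("^>", "", lines[is_header])
  ids <- sub("[[:space:]].*$", "", ids)
  seqs <- vapply(seq_along(ids), function(i) {
    toupper(paste(lines[grp == i & !is_header], collapse = ""))
  }, character(1))
  seqs <- gsub("[[:space:]]", "", seqs)
  n_sub <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, numeric(1)))
  if (n_sub > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_sub, " non-ACGTN characters replaced by N in ", path, call. = FALSE)
  }
  names(seqs) <- ids
  attr(seqs, "n_substituted") <- as.integer(n_sub)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
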