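# Low-level sequence helpers shared across modules. Sequences are plain
# upper-case character scalars over {A,C,G,T,N}; Biostrings does the
# alphabet-aware work (reverse complement, translation, motif matching).

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over \code{A,C,G,T,N}.
#' @return The reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

#' @keywords internal
assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  invisible(x)
}

# run a block with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random i.i.d. DNA at a target G+C (G and C equiprobable, likewise A/T)
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# the 64 codons in fixed lexicographic order (the canonical ordering used by
# every codon table and correlation in the package)
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

stop_codons <- function() c("TAA", "TAG", "TGA")
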