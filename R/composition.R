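# Nucleotide composition: whole-replicon G+C, sliding-window G+C and GC-skew
# profiles, cumulative-skew extrema (a proxy for replication origin/terminus
# in leading/lagging-strand-biased genomes) and plateau segmentation.
#
# Skew convention: (G - C)/(G + C) per window, 0 when a window has no G or C,
# so the cumulative series is total. With this sign the cumulative-skew
# minimum sits near oriC on genomes with the usual leading-strand G excess.

#' G+C content of a sequence
#'
#' N (and any ambiguity) is excluded from both numerator and denominator;
#' reports commonly express this as mol\% = fraction x 100.
#'
#' @param sequence DNA string over \code{A,C,G,T,N}.
#' @return Fraction in [0, 1].
#' @export
gc_content <- function(sequence) {
  assert_dna(sequence)
  counts <- base_counts(sequence)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L)
    stop("G+C content undefined: no unambiguous bases", call. = FALSE)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

base_counts <- function(sequence) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   letters = c("A", "C", "G", "T", "N"))
  stats::setNames(as.integer(f), c("A", "C", "G", "T", "N"))
}

#' Sliding-window G+C and GC-skew profile
#'
#' Windows of \code{window_size} bases every \code{step} bases. Circular
#' replicons wrap the end-start junction; on linear replicons the final short
#' window is kept and flagged. If \code{window_size} exceeds a linear
#' replicon's length a single whole-sequence window is returned with a
#' warning.
#'
#' @param x A \code{replicon}, or a DNA string (then \code{topology} applies).
#' @param window_size Window width in bases (default 10000).
#' @param step Step between window starts in bases (default 5000);
#'   \code{window_size >= step >= 1}.
#' @param topology Used only when \code{x} is a bare sequence.
#' @return An object of class \code{skew_profile}: list with
#'   \code{replicon_id}, \code{window_size}, \code{step}, \code{windows}
#'   (data frame: start, center, gc_fraction, skew, short), \code{cumulative}
#'   and \code{extrema}.
#' @export
sliding_windows <- function(x, window_size = 10000L, step = 5000L,
                            topology = "linear") {
  if (inherits(x, "replicon")) {
    sequence <- x$sequence; topology <- x$topology; id <- x$id
  } else {
    assert_dna(x); sequence <- x; id <- NA_character_
  }
  stopifnot(window_size >= step, step >= 1L)
  len <- nchar(sequence)
  if (window_size > len) {
    # a window can cover at most the whole molecule
    if (topology != "circular")
      warning("window_size > sequence length; using one whole-sequence window",
              call. = FALSE)
    window_size <- len
    step <- min(step, len)
    if (topology != "circular") step <- len
  }
  chars <- seq_chars(sequence)
  g <- cumsum(c(0L, chars == "G"))
  c_ <- cumsum(c(0L, chars == "C"))
  a <- cumsum(c(0L, chars == "A"))
  t_ <- cumsum(c(0L, chars == "T"))
  if (topology == "circular") {
    # extend the prefix sums across the junction
    ext <- function(cs, ch, letter) c(cs, cs[len + 1L] + cumsum(ch == letter))
    pre <- chars[seq_len(min(window_size - 1L, len))]
    g <- ext(g, pre, "G"); c_ <- ext(c_, pre, "C")
    a <- ext(a, pre, "A"); t_ <- ext(t_, pre, "T")
    starts <- seq(1L, len, by = step)
    ends <- starts + window_size - 1L
    short <- rep(FALSE, length(starts))
  } else {
    starts <- seq(1L, max(len - window_size + 1L, 1L), by = step)
    # keep a trailing short window when step tiling leaves a remainder
    if (max(starts) + window_size - 1L < len)
      starts <- c(starts, max(starts) + step)
    ends <- pmin(starts + window_size - 1L, len)
    short <- (ends - starts + 1L) < window_size
  }
  wg <- g[ends + 1L] - g[starts]
  wc <- c_[ends + 1L] - c_[starts]
  wa <- a[ends + 1L] - a[starts]
  wt <- t_[ends + 1L] - t_[starts]
  denom <- wg + wc + wa + wt
  gc_fraction <- ifelse(denom > 0L, (wg + wc) / denom, NA_real_)
  skew <- ifelse(wg + wc > 0L, (wg - wc) / (wg + wc), 0)
  center <- floor((starts + pmin(ends, starts + window_size - 1L)) / 2)
  windows <- data.frame(start = starts,
                        center = as.integer(center),
                        gc_fraction = gc_fraction, skew = skew, short = short)
  prof <- structure(list(replicon_id = id, window_size = window_size,
                         step = step, windows = windows,
                         cumulative = cumsum(skew), extrema = NULL),
                    class = "skew_profile")
  prof$extrema <- skew_extrema(prof)
  prof
}

#' Cumulative-skew extrema
#'
#' Window centers of the global maximum and minimum of the cumulative skew;
#' ties are broken toward the smallest center.
#'
#' @param profile A \code{skew_profile}.
#' @return Named integer vector \code{c(argmax_center, argmin_center)}.
#' @export
skew_extrema <- function(profile) {
  stopifnot(inherits(profile, "skew_profile"), nrow(profile$windows) > 0L)
  cum <- profile$cumulative
  centers <- profile$windows$center
  c(argmax_center = centers[which.max(cum)],
    argmin_center = centers[which.min(cum)])
}

#' Segment a skew profile into plateaus and signed runs
#'
#' Maximal runs of at least \code{min_run} consecutive windows with
#' \code{|skew| < slope_threshold} are labelled \code{"plateau"}; all other
#' windows are labelled by the sign of their skew. Sub-threshold runs shorter
#' than \code{min_run} are absorbed into a signed segment by the mean skew of
#' the run.
#'
#' @param profile A \code{skew_profile}.
#' @param slope_threshold Absolute per-window skew below which a window is a
#'   plateau candidate (default 0.02).
#' @param min_run Minimum number of consecutive windows for a plateau
#'   (default 10).
#' @return Data frame with \code{start_center}, \code{end_center},
#'   \code{label} in \code{"+", "-", "plateau"} and \code{n_windows}.
#' @export
skew_segments <- function(profile, slope_threshold = 0.02, min_run = 10L) {
  stopifnot(inherits(profile, "skew_profile"),
            slope_threshold > 0, min_run > 0L)
  w <- profile$windows
  lab <- ifelse(abs(w$skew) < slope_threshold, "plateau",
                ifelse(w$skew > 0, "+", "-"))
  r <- rle(lab)
  # demote short sub-threshold runs to the sign of their mean skew
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "plateau" && r$lengths[i] < min_run) {
      m <- mean(w$skew[starts[i]:ends[i]])
      r$values[i] <- if (m >= 0) "+" else "-"
    }
  }
  lab <- inverse.rle(r)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start_center = w$center[starts], end_center = w$center[ends],
             label = r$values, n_windows = r$lengths)
}

#' Per-replicon composition summary as a data frame
#'
#' @param g A \code{genome}.
#' @return Data frame: replicon_id, length, topology, gc_molpct.
#' @export
composition_summary <- function(g) {
  stopifnot(inherits(g, "genome"))
  data.frame(
    replicon_id = names(g$replicons),
    length = vapply(g$replicons, `[[`, integer(1), "length"),
    topology = vapply(g$replicons, `[[`, character(1), "topology"),
    gc_molpct = vapply(g$replicons, function(r) 100 * gc_content(r$sequence),
                       numeric(1)),
    row.names = NULL)
}
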