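## Tandem monomer scanning: exact occurrences of a repeat monomer (e.g. the
## vertebrate telomeric TTAGGG), chaining of occurrences into perfect arrays
## and interrupted "trains", and positional density profiles.

#' Scan a sequence for exact occurrences of a tandem monomer
#'
#' All exact occurrences are reported, including overlapping ones for
#' self-overlapping monomers (de-overlapping happens during array chaining).
#' With `both_strands`, occurrences of the reverse complement are reported
#' on the `-` strand (skipped if the monomer is its own reverse complement).
#'
#' @param sequence character scalar (ACGTN).
#' @param monomer monomer string, length >= 4, no N.
#' @param both_strands also scan for the reverse-complement monomer.
#' @return data frame with `start` (0-based), `strand`; sorted by start.
#' @export
scan_monomer <- function(sequence, monomer, both_strands = FALSE) {
  stopf(!grepl("N", monomer, fixed = TRUE), "monomer must not contain N")
  stopf(nchar(monomer) >= 4, "monomer length must be >= 4")
  subject <- Biostrings::DNAString(sequence)
  hit <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subject)
    if (!length(m)) return(NULL)
    data.frame(start = Biostrings::start(m) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- hit(monomer, "+")
  if (both_strands) {
    rc <- revcomp(monomer)
    if (rc != monomer) out <- rbind(out, hit(rc, "-"))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain monomer occurrences into tandem arrays and interrupted trains
#'
#' Occurrences spaced exactly one monomer length apart chain into perfect
#' arrays; spacings up to `max_spacer` bases chain into interrupted trains
#' (`interrupted = TRUE`). Overlapping occurrences of self-overlapping
#' monomers are consumed leftmost-greedily: an occurrence starting before
#' the current array's end extends nothing but belongs to that array.
#'
#' @param occurrences data frame from [scan_monomer()] (chained per strand),
#'   or a numeric vector of 0-based start positions.
#' @param monomer_length monomer length in bases.
#' @param max_spacer maximum interruption length bridged within a train.
#' @param min_copies arrays with fewer tandem copies are dropped
#'   (`min_copies = 1` keeps singletons, under which every occurrence
#'   belongs to exactly one reported array).
#' @return data frame: `start`, `end` (0-based half-open), `copy_number`,
#'   `interrupted`, `strand`.
#' @export
tandem_arrays <- function(occurrences, monomer_length, max_spacer = 0L,
                          min_copies = 2L) {
  if (is.numeric(occurrences)) {
    occurrences <- data.frame(start = as.integer(occurrences), strand = "+",
                              stringsAsFactors = FALSE)
  }
  out <- list()
  for (str in unique(occurrences$strand)) {
    pos <- sort(occurrences$start[occurrences$strand == str])
    if (!length(pos)) next
    s <- pos[1]; e <- pos[1] + monomer_length
    copies <- 1L; interrupted <- FALSE
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        start = s, end = e, copy_number = copies,
        interrupted = interrupted, strand = str, stringsAsFactors = FALSE)
    }
    for (p in pos[-1]) {
      if (p < e) next                       # overlapping duplicate, consumed
      gap <- p - e
      if (gap == 0L) {
        e <- p + monomer_length; copies <- copies + 1L
      } else if (gap <= max_spacer) {
        e <- p + monomer_length; copies <- copies + 1L; interrupted <- TRUE
      } else {
        flush()
        s <- p; e <- p + monomer_length; copies <- 1L; interrupted <- FALSE
      }
    }
    flush()
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      copy_number = integer(), interrupted = logical(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[res$copy_number >= min_copies, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-window occurrence density profile
#'
#' Counts occurrences in non-overlapping windows tiling the sequence; the
#' counts sum to the number of occurrences.
#'
#' @param occurrences data frame from [scan_monomer()] or numeric start
#'   positions.
#' @param sequence_length length of the scanned sequence.
#' @param window window size in bases (> 0).
#' @return data frame with `start`, `end`, `count` per window.
#' @export
density_profile <- function(occurrences, sequence_length, window) {
  stopf(window > 0, "window must be > 0")
  pos <- if (is.numeric(occurrences)) occurrences else occurrences$start
  n_win <- max(1L, as.integer(ceiling(sequence_length / window)))
  counts <- tabulate(pmin(floor(pos / window), n_win - 1L) + 1L, nbins = n_win)
  data.frame(start = (seq_len(n_win) - 1L) * window,
             end = pmin(seq_len(n_win) * window, sequence_length),
             count = counts)
}
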