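## Assembly QC statistics: Nx/Lx contiguity metrics, GC content in tiled
## windows with an N-fraction filter, and concordance classification of
## clone-end (BES-style) pair alignments.

#' Nx / Lx contiguity statistics
#'
#' Nx is the length of the record at which the cumulative sum of lengths,
#' taken in descending order, first reaches x percent of the total; Lx is the
#' number of records needed to reach it.
#'
#' @param lengths numeric vector of sequence lengths (> 0).
#' @param x_percent percentile, in (0, 100]; 50 gives the familiar N50/L50.
#' @return named numeric vector `c(Nx = ..., Lx = ...)`.
#' @export
nx_stats <- function(lengths, x_percent = 50) {
  stopf(length(lengths) > 0, "empty length list")
  stopf(all(lengths > 0), "lengths must be > 0")
  stopf(x_percent > 0 && x_percent <= 100, "x_percent must be in (0, 100]")
  lens <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= sum(lens) * x_percent / 100)[1]
  c(Nx = lens[i], Lx = i)
}

#' Assembly summary statistics
#'
#' @param seqs named character vector of sequences, or a numeric vector of
#'   lengths.
#' @return data frame with record count, total length, max length, N50 and
#'   L50.
#' @export
assembly_stats <- function(seqs) {
  lens <- if (is.character(seqs)) nchar(seqs) else as.numeric(seqs)
  n50 <- nx_stats(lens, 50)
  data.frame(n_records = length(lens), total_length = sum(lens),
             max_length = max(lens), N50 = unname(n50["Nx"]),
             L50 = unname(n50["Lx"]))
}

#' GC content over tiled windows
#'
#' Windows with more than `max_n_fraction` of N bases are discarded; GC is
#' computed over the non-N bases of each retained window. Windows tile each
#' sequence (stride = window by default; set a smaller stride for overlapping
#' sliding windows). The trailing partial window is kept if at least half a
#' window long.
#'
#' @param seqs named character vector of sequences (may contain N).
#' @param window window size in bases.
#' @param max_n_fraction maximum tolerated N fraction per window (strictly
#'   more than this is discarded).
#' @param stride distance between window starts; defaults to `window`
#'   (non-overlapping tiles).
#' @return data frame with `sequence_id`, `start`, `end` (0-based half-open),
#'   `gc` (percent over non-N bases), `n_fraction`. Zero rows (with a
#'   warning) if every window was discarded.
#' @export
gc_windows <- function(seqs, window = 20000L, max_n_fraction = 0.25,
                       stride = NULL) {
  stopf(length(seqs) > 0, "no sequences")
  if (is.null(stride)) stride <- window
  out <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    starts <- seq(0L, max(L - window, 0L), by = stride)
    ends <- pmin(starts + window, L)
    keep <- ends - starts >= window / 2
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    v <- Biostrings::DNAString(seqs[[id]])
    freq <- Biostrings::letterFrequency(
      Biostrings::Views(v, start = starts + 1L, end = ends),
      letters = c("G", "C", "N"))
    wlen <- ends - starts
    n_frac <- freq[, "N"] / wlen
    gc <- 100 * (freq[, "G"] + freq[, "C"]) / pmax(wlen - freq[, "N"], 1)
    sel <- n_frac <= max_n_fraction
    if (any(sel)) {
      out[[id]] <- data.frame(sequence_id = id, start = starts[sel],
                              end = ends[sel], gc = gc[sel],
                              n_fraction = n_frac[sel],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    warning("all windows discarded (N fraction above threshold)")
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), gc = numeric(), n_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Classify clone-end pair alignments by concordance
#'
#' Each pair carries up to two end placements. A pair is
#' `same_scaffold_proper` when both ends hit one target in convergent
#' orientation (the `+` end upstream of the `-` end, pointing at each other)
#' and their outermost coordinates are separated by a distance in
#' `[d_min, d_max]` -- the expected clone insert size; `same_scaffold_improper`
#' when on one target but failing orientation or separation;
#' `different_scaffold` when the two ends hit different targets; `orphan`
#' when fewer than two ends aligned.
#'
#' @param pairs data frame with one row per aligned end: `pair_id`, `end`
#'   (1 or 2), `target_id`, `start`, `end_pos` (0-based half-open), `strand`.
#'   Pairs absent or with a single row are orphans.
#' @param d_min,d_max allowed separation between outermost aligned
#'   coordinates (defaults 50 kb--250 kb).
#' @return list with `pairs` (per-pair classification) and `summary` (counts
#'   and fractions per category; fractions sum to 1).
#' @export
classify_end_pairs <- function(pairs, d_min = 50000, d_max = 250000) {
  need <- c("pair_id", "end", "target_id", "start", "end_pos", "strand")
  stopf(all(need %in% names(pairs)), "pairs needs columns: %s",
        paste(need, collapse = ", "))
  stopf(!any(duplicated(pairs[, c("pair_id", "end")])),
        "duplicate pair_id/end combination")
  ids <- unique(pairs$pair_id)
  cls <- character(length(ids))
  for (i in seq_along(ids)) {
    rows <- pairs[pairs$pair_id == ids[i], , drop = FALSE]
    if (nrow(rows) < 2) { cls[i] <- "orphan"; next }
    if (length(unique(rows$target_id)) > 1) { cls[i] <- "different_scaffold"; next }
    a <- rows[1, ]; b <- rows[2, ]
    sep <- max(a$end_pos, b$end_pos) - min(a$start, b$start)
    convergent <- a$strand != b$strand &&
      (if (a$strand == "+") a$start <= b$start else b$start <= a$start)
    cls[i] <- if (convergent && sep >= d_min && sep <= d_max)
      "same_scaffold_proper" else "same_scaffold_improper"
  }
  lev <- c("same_scaffold_proper", "same_scaffold_improper",
           "different_scaffold", "orphan")
  counts <- table(factor(cls, levels = lev))
  list(pairs = data.frame(pair_id = ids, classification = cls,
                          stringsAsFactors = FALSE),
       summary = data.frame(classification = lev,
                            count = as.integer(counts),
                            fraction = as.numeric(counts) / length(ids),
                            stringsAsFactors = FALSE))
}
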