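## Contig end-overlap gap closure: detect end-of-left to start-of-right
## overlaps between neighbouring contigs in a scaffold layout and merge them
## by trimming the overlap from the left contig and concatenating the right
## one. Only +/+ overlaps (after orientation normalization) are used.

## Oriented sequence of a contig as it appears in the scaffold.
oriented_seq <- function(contigs, id, orientation) {
  s <- contigs[[id]]
  if (orientation == "-") revcomp(s) else s
}

## Best end-to-start overlap between oriented sequences a and b.
## Seeds on the terminal 20-mers of a (several back-offsets tolerate
## mismatches in the extreme tail), candidates verified by full ungapped
## comparison of suffix(a, o) vs prefix(b, o).
best_overlap <- function(a, b, min_identity, min_len, end_window) {
  la <- nchar(a); lb <- nchar(b)
  wb <- min(end_window, lb)
  b_head <- Biostrings::DNAString(subseq0(b, 0L, wb))
  best <- NULL
  for (off in c(0L, 7L, 13L, 29L)) {
    if (la - off < 20L) break
    seed <- subseq0(a, la - off - 20L, la - off)
    m <- Biostrings::matchPattern(seed, b_head)
    for (e in Biostrings::end(m)) {
      o <- e + off                       # implied overlap length
      if (o < min_len || o > min(la, lb) || o > end_window) next
      sa <- charToRaw(subseq0(a, la - o, la))
      sb <- charToRaw(subseq0(b, 0L, o))
      id <- 100 * sum(sa == sb) / o
      if (id >= min_identity && (is.null(best) || o > best$overlap_length)) {
        best <- list(overlap_length = o, identity = id)
      }
    }
  }
  best
}

#' Find end-to-start overlaps between neighbouring contigs
#'
#' For each neighbouring pair (a, b) in each scaffold of the layout, contigs
#' are first orientation-normalized (so all comparisons are +/+), and the
#' suffix of a is compared against the prefix of b within `end_window` of the
#' termini. The longest overlap of at least `min_len` bases reaching
#' `min_identity` percent ungapped identity is reported per pair.
#' Reverse-strand end matches are never considered.
#'
#' @param layout data frame with `object`, `rank`, `contig_id`,
#'   `orientation` (e.g. the ordering from [order_contigs()] or a layout
#'   from [read_agp()]).
#' @param contigs named character vector of contig sequences (unoriented).
#' @param min_identity minimum percent identity of the overlap.
#' @param min_len minimum overlap length in bases.
#' @param end_window how far from the contig termini an overlap may extend.
#' @return data frame: `object`, `left_contig`, `right_contig`,
#'   `overlap_length`, `identity`.
#' @export
find_end_overlaps <- function(layout, contigs, min_identity = 95,
                              min_len = 100L, end_window = 10000L) {
  out <- list()
  for (obj in unique(layout$object)) {
    rows <- layout[layout$object == obj, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    if (nrow(rows) < 2) next
    for (i in seq_len(nrow(rows) - 1L)) {
      a <- oriented_seq(contigs, rows$contig_id[i], rows$orientation[i])
      b <- oriented_seq(contigs, rows$contig_id[i + 1L], rows$orientation[i + 1L])
      ov <- best_overlap(a, b, min_identity, min_len, end_window)
      if (!is.null(ov)) {
        out[[length(out) + 1L]] <- data.frame(
          object = obj, left_contig = rows$contig_id[i],
          right_contig = rows$contig_id[i + 1L],
          overlap_length = ov$overlap_length, identity = ov$identity,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(object = character(), left_contig = character(),
                      right_contig = character(), overlap_length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Close scaffold gaps by trim-and-concatenate merging
#'
#' Every junction with a detected overlap is closed by trimming the overlap
#' region from the left contig and concatenating the right contig (the
#' right contig's copy of the overlap is kept verbatim). Merges propagate
#' transitively along a scaffold, so a run of overlapping neighbours
#' collapses into one contig of length `sum(lengths) - sum(overlaps)`.
#'
#' @param layout as in [find_end_overlaps()].
#' @param contigs named character vector of contig sequences.
#' @param overlaps data frame from [find_end_overlaps()].
#' @return list with `contigs` (merged contig set, merged records named
#'   after their first member), `layout` (updated layout, all `+`
#'   orientation for merged records), and `report`
#'   (`total_gaps`, `gaps_closed`, `closed_fraction`, `n50_before`,
#'   `n50_after`).
#' @export
close_gaps <- function(layout, contigs, overlaps) {
  key <- function(a, b) paste(a, b, sep = "\r")
  ov <- setNames(overlaps$overlap_length,
                 key(overlaps$left_contig, overlaps$right_contig))
  new_contigs <- character(0); new_layout <- list()
  total_gaps <- 0L; closed <- 0L
  for (obj in unique(layout$object)) {
    rows <- layout[layout$object == obj, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    total_gaps <- total_gaps + max(nrow(rows) - 1L, 0L)
    cur_seq <- oriented_seq(contigs, rows$contig_id[1], rows$orientation[1])
    cur_name <- rows$contig_id[1]
    cur_merged <- FALSE
    pieces <- list()
    for (i in seq_len(nrow(rows))[-1]) {
      k <- key(rows$contig_id[i - 1L], rows$contig_id[i])
      nxt <- oriented_seq(contigs, rows$contig_id[i], rows$orientation[i])
      if (!is.na(ov[k])) {
        o <- ov[[k]]
        if (o >= nchar(cur_seq)) {
          stop(sprintf("inconsistent chained trim at pair %s-%s",
                       rows$contig_id[i - 1L], rows$contig_id[i]), call. = FALSE)
        }
        cur_seq <- paste0(subseq0(cur_seq, 0L, nchar(cur_seq) - o), nxt)
        cur_merged <- TRUE
        closed <- closed + 1L
      } else {
        pieces[[length(pieces) + 1L]] <-
          list(name = cur_name, seq = cur_seq, merged = cur_merged,
               orientation = if (cur_merged) "+" else
                 rows$orientation[match(cur_name, rows$contig_id)])
        cur_seq <- nxt; cur_name <- rows$contig_id[i]; cur_merged <- FALSE
      }
    }
    pieces[[length(pieces) + 1L]] <-
      list(name = cur_name, seq = cur_seq, merged = cur_merged,
           orientation = if (cur_merged) "+" else
             rows$orientation[match(cur_name, rows$contig_id)])
    for (j in seq_along(pieces)) {
      p <- pieces[[j]]
      ## merged records are stored in scaffold orientation; untouched
      ## contigs keep their original sequence and layout orientation
      new_contigs[[p$name]] <- if (p$merged) p$seq else contigs[[p$name]]
      new_layout[[length(new_layout) + 1L]] <-
        data.frame(object = obj, rank = j, contig_id = p$name,
                   orientation = p$orientation, stringsAsFactors = FALSE)
    }
  }
  lens_before <- nchar(contigs[unique(layout$contig_id)])
  lens_after <- nchar(new_contigs)
  list(contigs = new_contigs,
       layout = do.call(rbind, new_layout),
       report = list(total_gaps = total_gaps, gaps_closed = closed,
                     closed_fraction = if (total_gaps > 0) closed / total_gaps else NA_real_,
                     n50_before = unname(nx_stats(lens_before)["Nx"]),
                     n50_after = unname(nx_stats(lens_after)["Nx"])))
}
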