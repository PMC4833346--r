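## Linkage-map marker anchoring: filter marker-to-assembly alignment hits
## (top-5 by score, best alignment coverage, identity >= 90%, coverage >=
## 80%), assign scaffolds to linkage groups by plurality vote of their
## retained markers, and summarize anchoring completeness.

#' Filter marker alignment hits
#'
#' Per marker: (1) keep the top `top_n` hits by alignment score (ties at the
#' last rank all kept); (2) among those, keep the hit(s) with the maximal
#' marker alignment coverage -- when several targets tie on coverage, all are
#' retained; (3) drop hits below the identity or coverage thresholds. The
#' filter is idempotent.
#'
#' @param hits data frame with columns `marker_id`, `linkage_group`,
#'   `target_id`, `identity` (percent), `coverage` (percent of marker length
#'   aligned), `score`.
#' @param min_identity,min_coverage retention thresholds (percent).
#' @param top_n number of top-scoring hits considered per marker.
#' @return filtered data frame (possibly zero rows).
#' @export
filter_marker_hits <- function(hits, min_identity = 90, min_coverage = 80,
                               top_n = 5L) {
  need <- c("marker_id", "target_id", "identity", "coverage", "score")
  stopf(all(need %in% names(hits)), "hits needs columns: %s",
        paste(need, collapse = ", "))
  if (nrow(hits) == 0) return(hits)
  keep <- logical(nrow(hits))
  for (m in unique(hits$marker_id)) {
    idx <- which(hits$marker_id == m)
    sc <- hits$score[idx]
    if (length(idx) > top_n) {
      cut <- sort(sc, decreasing = TRUE)[top_n]
      idx <- idx[sc >= cut]          # ties at rank top_n are all kept
    }
    best_cov <- max(hits$coverage[idx])
    idx <- idx[hits$coverage[idx] == best_cov]
    idx <- idx[hits$identity[idx] >= min_identity &
                 hits$coverage[idx] >= min_coverage]
    keep[idx] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign targets to linkage groups by marker plurality
#'
#' Votes are counted per target as the number of distinct retained markers
#' from each linkage group (a marker hitting the same target several times
#' counts once). The linkage group with the most votes wins; a tie for the
#' maximum leaves the target `conflicted` and unassigned.
#'
#' @param retained_hits output of [filter_marker_hits()]; must carry a
#'   `linkage_group` column.
#' @return data frame with `target_id`, `assigned_lg` (NA when conflicted),
#'   `n_markers`, `top_votes`, `status`
#'   (`unambiguous` | `majority` | `conflicted`), and a `votes` list-column
#'   of named per-LG counts.
#' @export
assign_linkage_groups <- function(retained_hits) {
  stopf("linkage_group" %in% names(retained_hits),
        "retained_hits needs a linkage_group column")
  h <- unique(retained_hits[, c("marker_id", "linkage_group", "target_id")])
  targets <- unique(h$target_id)
  res <- lapply(targets, function(tg) {
    votes <- table(h$linkage_group[h$target_id == tg])
    top <- max(votes)
    winners <- names(votes)[votes == top]
    status <- if (length(winners) > 1) "conflicted"
              else if (length(votes) == 1) "unambiguous" else "majority"
    data.frame(target_id = tg,
               assigned_lg = if (status == "conflicted") NA_character_ else winners,
               n_markers = sum(votes), top_votes = as.integer(top),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$votes <- lapply(targets, function(tg) {
    v <- table(h$linkage_group[h$target_id == tg])
    setNames(as.integer(v), names(v))
  })
  out
}

#' Anchoring completeness summary
#'
#' @param assignments output of [assign_linkage_groups()].
#' @param retained_hits the filtered hits used for the assignment.
#' @param n_markers_total total number of markers attempted (denominator of
#'   the placed-marker fraction).
#' @param assembly named character vector of sequences or named numeric
#'   lengths for the full assembly.
#' @return named numeric vector: `marker_fraction` (markers retained on an
#'   LG-assigned target / total) and `length_fraction` (assembly length on
#'   assigned targets / total length).
#' @export
anchoring_summary <- function(assignments, retained_hits, n_markers_total,
                              assembly) {
  lens <- if (is.character(assembly)) nchar(assembly) else as.numeric(assembly)
  assigned <- assignments$target_id[!is.na(assignments$assigned_lg)]
  placed <- unique(retained_hits$marker_id[retained_hits$target_id %in% assigned])
  c(marker_fraction = length(placed) / n_markers_total,
    length_fraction = sum(lens[names(lens) %in% assigned]) / sum(lens))
}

#' Score marker sequences against contigs by exact placement
#'
#' A lightweight alignment stand-in for simulated data: each marker is
#' searched against each contig (both strands) for its best ungapped match
#' anchored at an exact 16-mer seed; identity and coverage are computed from
#' the best extension. Real analyses should import aligner output with
#' [read_alignments()] instead.
#'
#' @param markers named character vector of marker sequences.
#' @param contigs named character vector of contig sequences.
#' @param lg_map named character vector mapping marker_id to linkage group.
#' @return hit data frame suitable for [filter_marker_hits()].
#' @export
align_markers <- function(markers, contigs, lg_map) {
  subject <- Biostrings::DNAStringSet(contigs)
  hits <- list()
  for (m in names(markers)) {
    q <- markers[[m]]
    best <- NULL
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q else revcomp(q)
      seed <- substr(qs, 1, 16)
      idx <- Biostrings::vwhichPDict(
        Biostrings::PDict(Biostrings::DNAStringSet(seed)), subject)
      for (ci in seq_along(subject)) {
        if (!length(idx[[ci]])) next
        starts <- Biostrings::start(
          Biostrings::matchPattern(seed, subject[[ci]]))
        for (s in starts) {
          e <- s + nchar(qs) - 1L
          if (e > length(subject[[ci]])) next
          tgt <- as.character(Biostrings::subseq(subject[[ci]], s, e))
          mism <- sum(charToRaw(tgt) != charToRaw(qs))
          id <- 100 * (1 - mism / nchar(qs))
          cand <- data.frame(marker_id = m,
                             linkage_group = unname(lg_map[m]),
                             target_id = names(contigs)[ci],
                             target_start = s - 1L, target_end = e,
                             strand = strand, identity = id, coverage = 100,
                             score = id * nchar(qs) / 100,
                             stringsAsFactors = FALSE)
          if (is.null(best) || cand$score > best$score) best <- cand
        }
      }
    }
    if (!is.null(best)) hits[[m]] <- best
  }
  if (!length(hits)) {
    return(data.frame(marker_id = character(), linkage_group = character(),
                      target_id = character(), target_start = integer(),
                      target_end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, unname(hits))
  rownames(out) <- NULL
  out
}
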