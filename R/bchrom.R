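## B-chromosome pseudo-scaffolds: chain mapped-read placements across
## sub-threshold gaps and summarize the homology composition of the chained
## intervals by linkage group.

#' Chain read placements into pseudo-scaffolds
#'
#' Per target sequence, placements are sorted and merged whenever the gap to
#' the next interval (`next start - current end`) is strictly less than
#' `max_gap`. The merged intervals are disjoint with pairwise gaps of at
#' least `max_gap`, and the result is independent of input order.
#'
#' @param placements data frame with `target_id`, `start`, `end` (0-based
#'   half-open read placements).
#' @param max_gap chaining threshold in bases (strict `<`).
#' @return data frame: `target_id`, `start`, `end`, `n_members`, `span`.
#' @export
chain_placements <- function(placements, max_gap = 10000L) {
  need <- c("target_id", "start", "end")
  stopf(all(need %in% names(placements)), "placements needs columns: %s",
        paste(need, collapse = ", "))
  stopf(all(placements$end >= placements$start),
        "negative-length interval in placements")
  out <- list()
  for (tg in unique(placements$target_id)) {
    p <- placements[placements$target_id == tg, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    s <- p$start[1]; e <- p$end[1]; n <- 1L
    for (i in seq_len(nrow(p))[-1]) {
      if (p$start[i] - e < max_gap) {
        e <- max(e, p$end[i]); n <- n + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(target_id = tg, start = s,
                                              end = e, n_members = n,
                                              stringsAsFactors = FALSE)
        s <- p$start[i]; e <- p$end[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(target_id = tg, start = s, end = e,
                                          n_members = n, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(target_id = character(), start = integer(),
                      end = integer(), n_members = integer(), span = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$span <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Linkage-group composition of pseudo-scaffolds
#'
#' Sums pseudo-scaffold spans per linkage group of their target sequences;
#' targets without an assignment (absent from `lg_assignments` or with a
#' conflicted `NA` assignment) fall into an `"unassigned"` bucket. Spans
#' conserve the total.
#'
#' @param pseudo_scaffolds data frame from [chain_placements()].
#' @param lg_assignments data frame with `target_id`, `assigned_lg` (e.g.
#'   from [assign_linkage_groups()]); may be NULL (all unassigned).
#' @return data frame: `lg`, `span`, `fraction`, sorted by decreasing span.
#' @export
homology_composition <- function(pseudo_scaffolds, lg_assignments = NULL) {
  if (nrow(pseudo_scaffolds) == 0) {
    return(data.frame(lg = character(), span = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  lg <- rep("unassigned", nrow(pseudo_scaffolds))
  if (!is.null(lg_assignments) && nrow(lg_assignments) > 0) {
    m <- match(pseudo_scaffolds$target_id, lg_assignments$target_id)
    assigned <- !is.na(m) & !is.na(lg_assignments$assigned_lg[m])
    lg[assigned] <- lg_assignments$assigned_lg[m[assigned]]
  }
  span <- tapply(pseudo_scaffolds$span, lg, sum)
  res <- data.frame(lg = names(span), span = as.numeric(span),
                    fraction = as.numeric(span) / sum(pseudo_scaffolds$span),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$span), , drop = FALSE]
  rownames(res) <- NULL
  res
}
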