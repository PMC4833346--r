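## Reference-guided scaffolding from alignment tables: 1:1 filtering,
## two-pass collinear block construction, block statistics and rearrangement
## census, contig ordering/orientation against reference chromosomes,
## reconciliation of contig links against independent ordering evidence, and
## AGP/FASTA scaffold emission.

## Does interval [s, e) overlap any accepted interval in `acc` (2-col matrix)?
overlaps_any <- function(acc, s, e) {
  nrow(acc) > 0 && any(s < acc[, 2] & e > acc[, 1])
}

## Required left/right trims (in bases) for interval [s, e) against a set of
## accepted intervals; NA when an accepted interval lies strictly inside.
end_trims <- function(acc, s, e) {
  lt <- 0; rt <- 0
  if (nrow(acc)) {
    for (j in seq_len(nrow(acc))) {
      a <- acc[j, 1]; b <- acc[j, 2]
      if (b <= s || a >= e) next
      if (a <= s && b >= e) return(c(NA_real_, NA_real_))  # fully covered
      if (a <= s) lt <- max(lt, b - s)
      else if (b >= e) rt <- max(rt, e - a)
      else return(c(NA_real_, NA_real_))                   # strictly inside
    }
  }
  c(lt, rt)
}

#' Filter alignments to 1:1 coverage
#'
#' Greedy by descending score: each alignment is kept only where it does not
#' overlap previously retained alignments on either its query or its target
#' sequence. End overlaps are trimmed off (the trim is applied to both
#' coordinate systems, respecting strand); alignments fully covered, split
#' by an interior overlap, or left shorter than `min_keep` are dropped. The
#' result covers every query and target position at most once.
#'
#' @param aln normalized alignment data frame (see [read_alignments()]).
#' @param min_keep minimum surviving alignment length after trimming.
#' @return the retained (possibly trimmed) subset, in the original row
#'   order; `length` and `score` are rescaled proportionally on trim.
#' @export
filter_one_to_one <- function(aln, min_keep = 100L) {
  if (nrow(aln) == 0) return(aln)
  ord <- order(-aln$score)
  q_acc <- list(); t_acc <- list()
  keep <- logical(nrow(aln))
  for (i in ord) {
    q <- aln$query_id[i]; tg <- aln$target_id[i]
    qa <- q_acc[[q]]; ta <- t_acc[[tg]]
    if (is.null(qa)) qa <- matrix(numeric(0), 0, 2)
    if (is.null(ta)) ta <- matrix(numeric(0), 0, 2)
    qs <- aln$query_start[i]; qe <- aln$query_end[i]
    ts <- aln$target_start[i]; te <- aln$target_end[i]
    plus <- aln$strand[i] == "+"
    len0 <- qe - qs
    ok <- FALSE
    for (iter in 1:8) {
      qt <- end_trims(qa, qs, qe)
      tt <- end_trims(ta, ts, te)
      if (anyNA(qt) || anyNA(tt)) break
      ## translate target trims into alignment head/tail trims
      head_trim <- max(qt[1], if (plus) tt[1] else tt[2])
      tail_trim <- max(qt[2], if (plus) tt[2] else tt[1])
      if (head_trim == 0 && tail_trim == 0) { ok <- TRUE; break }
      qs <- qs + head_trim; qe <- qe - tail_trim
      if (plus) { ts <- ts + head_trim; te <- te - tail_trim }
      else      { ts <- ts + tail_trim; te <- te - head_trim }
      if (qe - qs < min_keep || te - ts < min_keep) break
    }
    if (!ok || qe - qs < min_keep) next
    keep[i] <- TRUE
    frac <- (qe - qs) / len0
    aln$query_start[i] <- qs; aln$query_end[i] <- qe
    aln$target_start[i] <- ts; aln$target_end[i] <- te
    aln$length[i] <- round(aln$length[i] * frac)
    aln$score[i] <- aln$score[i] * frac
    q_acc[[q]] <- rbind(qa, c(qs, qe))
    t_acc[[tg]] <- rbind(ta, c(ts, te))
  }
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Chain a sorted group of same-(query,target,strand) alignments into
## collinear runs: monotone in both coordinates, gaps within max_gap.
chain_group <- function(g, max_gap) {
  g <- g[order(g$query_start), , drop = FALSE]
  minus <- g$strand[1] == "-"
  runs <- list(); cur <- 1L
  for (i in seq_len(nrow(g))[-1]) {
    prev <- g[i - 1L, ]; this <- g[i, ]
    qgap <- this$query_start - prev$query_end
    tgap <- if (minus) prev$target_start - this$target_end
            else this$target_start - prev$target_end
    ok <- qgap >= 0 && qgap <= max_gap && tgap >= 0 && tgap <= max_gap
    if (!ok) { runs[[length(runs) + 1L]] <- cur; cur <- integer(0) }
    cur <- c(cur, i)
  }
  runs[[length(runs) + 1L]] <- cur
  lapply(runs, function(idx) g[idx, , drop = FALSE])
}

run_to_block <- function(run) {
  data.frame(query_id = run$query_id[1],
             query_start = min(run$query_start),
             query_end = max(run$query_end),
             target_id = run$target_id[1],
             target_start = min(run$target_start),
             target_end = max(run$target_end),
             orientation = run$strand[1],
             n_members = nrow(run),
             span_length = max(run$query_end) - min(run$query_start),
             stringsAsFactors = FALSE)
}

chain_pass <- function(aln, max_gap) {
  key <- paste(aln$query_id, aln$target_id, aln$strand, sep = "\r")
  groups <- split(aln, key)
  blocks <- list(); members <- list()
  for (g in groups) {
    for (run in chain_group(g, max_gap)) {
      blocks[[length(blocks) + 1L]] <- run_to_block(run)
      members[[length(members) + 1L]] <- run
    }
  }
  list(blocks = do.call(rbind, blocks), members = members)
}

#' Build collinear synteny blocks by two-pass chaining
#'
#' Pass 1 chains 1:1-filtered alignments that share query, target and
#' orientation and are collinear in both genomes within `max_gap`. Blocks
#' spanning less than `min_block` on the query are treated as spurious: their
#' member alignments are removed and the remainder re-chained (pass 2), which
#' lets collinear runs previously interrupted by a short discordant block
#' merge into larger blocks. Blocks still shorter than `min_block` after
#' pass 2 are dropped (strictly-less-than comparison: a block of exactly
#' `min_block` is retained).
#'
#' @param aln normalized, 1:1-filtered alignment data frame.
#' @param min_block minimum retained block span on the query, in bases.
#' @param max_gap maximum collinear gap bridged when chaining, in bases.
#' @return block data frame: `query_id`, `query_start`, `query_end`,
#'   `target_id`, `target_start`, `target_end`, `orientation`, `n_members`,
#'   `span_length`.
#' @export
build_blocks <- function(aln, min_block = 6000L, max_gap = 50000L) {
  if (nrow(aln) == 0) {
    return(data.frame(query_id = character(), query_start = integer(),
                      query_end = integer(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      orientation = character(), n_members = integer(),
                      span_length = integer(), stringsAsFactors = FALSE))
  }
  p1 <- chain_pass(aln, max_gap)
  spurious <- which(p1$blocks$span_length < min_block)
  if (length(spurious)) {
    drop_rows <- do.call(rbind, p1$members[spurious])
    sig <- function(d) paste(d$query_id, d$query_start, d$query_end,
                             d$target_id, d$target_start, sep = "\r")
    aln2 <- aln[!(sig(aln) %in% sig(drop_rows)), , drop = FALSE]
    p2 <- if (nrow(aln2)) chain_pass(aln2, max_gap) else list(blocks = NULL)
  } else {
    p2 <- p1
  }
  blocks <- p2$blocks
  if (is.null(blocks)) return(build_blocks(aln[0, ], min_block, max_gap))
  blocks <- blocks[blocks$span_length >= min_block, , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Block coverage, N50 and intrachromosomal rearrangement census
#'
#' Coverage is the fraction of the query assembly inside block query spans;
#' block N50 follows [nx_stats()] on query spans. The rearrangement census
#' works per target chromosome: the dominant orientation is the
#' span-weighted majority, and maximal runs of target-adjacent blocks in the
#' minority orientation (joined across target gaps up to `max_join`) are
#' counted as one rearrangement each when their combined target span exceeds
#' `rearrangement_min`. This captures inversions irrespective of how finely
#' the query side is fragmented into contigs.
#'
#' @param blocks output of [build_blocks()].
#' @param assembly named character vector of query sequences, or named
#'   lengths.
#' @param rearrangement_min minimum rearranged span counted, in bases.
#' @param max_join maximum target gap when merging adjacent rearranged
#'   blocks into one event.
#' @return list with `coverage` (fraction), `block_n50`, `n_blocks`,
#'   `rearrangements` (count) and `rearrangement_spans`.
#' @export
block_stats <- function(blocks, assembly, rearrangement_min = 200000L,
                        max_join = 50000L) {
  lens <- if (is.character(assembly)) nchar(assembly) else as.numeric(assembly)
  total <- sum(lens)
  if (nrow(blocks) == 0) {
    return(list(coverage = 0, block_n50 = 0, n_blocks = 0L,
                rearrangements = 0L, rearrangement_spans = numeric(0)))
  }
  cov <- sum(blocks$span_length) / total
  n50 <- unname(nx_stats(blocks$span_length, 50)["Nx"])
  spans <- numeric(0)
  for (tg in unique(blocks$target_id)) {
    b <- blocks[blocks$target_id == tg, , drop = FALSE]
    b <- b[order(b$target_start), , drop = FALSE]
    w <- tapply(b$span_length, b$orientation, sum)
    dominant <- names(w)[which.max(w)]
    minority <- which(b$orientation != dominant)
    if (!length(minority)) next
    ## merge target-adjacent minority blocks into events
    run_start <- b$target_start[minority]
    run_end <- b$target_end[minority]
    o <- order(run_start)
    run_start <- run_start[o]; run_end <- run_end[o]
    ev_s <- run_start[1]; ev_e <- run_end[1]
    for (i in seq_along(run_start)[-1]) {
      if (run_start[i] - ev_e <= max_join) {
        ev_e <- max(ev_e, run_end[i])
      } else {
        spans <- c(spans, ev_e - ev_s)
        ev_s <- run_start[i]; ev_e <- run_end[i]
      }
    }
    spans <- c(spans, ev_e - ev_s)
  }
  spans <- spans[spans > rearrangement_min]
  list(coverage = cov, block_n50 = n50, n_blocks = nrow(blocks),
       rearrangements = length(spans), rearrangement_spans = spans)
}

#' Order and orient contigs along reference chromosomes
#'
#' Each contig's dominant placement is the reference chromosome holding the
#' largest summed block span; the placement must also be clearly dominant —
#' a contig whose runner-up chromosome holds more than `ambiguity` times the
#' dominant span (e.g. a 60/40 split at the default 0.5) is reported
#' unplaced rather than guessed. Placed contigs are sorted by the
#' span-weighted midpoint of their blocks on the dominant chromosome;
#' orientation is the span-weighted majority of block orientations there.
#'
#' @param blocks output of [build_blocks()] (query_id = contig).
#' @param ambiguity maximum tolerated runner-up/dominant span ratio.
#' @return list with `ordering` (data frame: `object` = reference
#'   chromosome, `rank`, `contig_id`, `orientation`, `ref_pos`) and
#'   `unplaced` (data frame of contig_id and reason).
#' @export
order_contigs <- function(blocks, ambiguity = 0.5) {
  placed <- list(); unplaced <- list()
  for (ctg in unique(blocks$query_id)) {
    b <- blocks[blocks$query_id == ctg, , drop = FALSE]
    by_tgt <- tapply(b$span_length, b$target_id, sum)
    dom <- names(by_tgt)[which.max(by_tgt)]
    runner_up <- if (length(by_tgt) > 1) max(by_tgt[names(by_tgt) != dom]) else 0
    if (runner_up > ambiguity * max(by_tgt)) {
      unplaced[[ctg]] <- data.frame(contig_id = ctg,
                                    reason = "ambiguous chromosome placement",
                                    stringsAsFactors = FALSE)
      next
    }
    bd <- b[b$target_id == dom, , drop = FALSE]
    wt <- bd$span_length
    mid <- (bd$target_start + bd$target_end) / 2
    ori_w <- tapply(wt, bd$orientation, sum)
    placed[[ctg]] <- data.frame(object = dom, contig_id = ctg,
                                orientation = names(ori_w)[which.max(ori_w)],
                                ref_pos = sum(mid * wt) / sum(wt),
                                stringsAsFactors = FALSE)
  }
  ordering <- if (length(placed)) do.call(rbind, unname(placed)) else
    data.frame(object = character(), contig_id = character(),
               orientation = character(), ref_pos = numeric(),
               stringsAsFactors = FALSE)
  ordering <- ordering[order(ordering$object, ordering$ref_pos), , drop = FALSE]
  ordering$rank <- stats::ave(seq_len(nrow(ordering)), ordering$object,
                              FUN = seq_along)
  rownames(ordering) <- NULL
  list(ordering = ordering[, c("object", "rank", "contig_id", "orientation",
                               "ref_pos")],
       unplaced = if (length(unplaced)) do.call(rbind, unname(unplaced)) else
         data.frame(contig_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Derive contig adjacency links from an ordering
#'
#' @param ordering the `ordering` component of [order_contigs()].
#' @param evidence evidence tag stored on each link.
#' @return data frame of links: `left_contig`, `left_orientation`,
#'   `right_contig`, `right_orientation`, `evidence`, `object`.
#' @export
links_from_ordering <- function(ordering, evidence = "synteny") {
  out <- list()
  for (obj in unique(ordering$object)) {
    rows <- ordering[ordering$object == obj, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    if (nrow(rows) < 2) next
    n <- nrow(rows)
    out[[obj]] <- data.frame(left_contig = rows$contig_id[-n],
                             left_orientation = rows$orientation[-n],
                             right_contig = rows$contig_id[-1],
                             right_orientation = rows$orientation[-1],
                             evidence = evidence, object = obj,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(left_contig = character(), left_orientation = character(),
                      right_contig = character(), right_orientation = character(),
                      evidence = character(), object = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Reconcile contig links against independent ordering evidence
#'
#' A link is rejected when (a) an independent constraint order (e.g. an
#' optical-map contig sequence) contains both of its contigs at
#' non-adjacent positions, or (b) its contigs are assigned to different
#' linkage groups. Among surviving links, later duplicates of an already
#' used contig side are rejected so that accepted links form simple paths;
#' a cycle among accepted links is an error.
#'
#' @param links data frame as from [links_from_ordering()].
#' @param constraint_orders list of character vectors, each an independently
#'   derived contig order.
#' @param lg_assignments optional data frame from
#'   [assign_linkage_groups()] (`target_id`, `assigned_lg`).
#' @return list with `accepted` and `rejected` (the latter with a `reason`
#'   column).
#' @export
reconcile_links <- function(links, constraint_orders = list(),
                            lg_assignments = NULL) {
  if (nrow(links) == 0) return(list(accepted = links, rejected = cbind(links, reason = character(0))))
  reason <- rep(NA_character_, nrow(links))
  lg <- NULL
  if (!is.null(lg_assignments)) {
    lg <- setNames(lg_assignments$assigned_lg, lg_assignments$target_id)
  }
  for (i in seq_len(nrow(links))) {
    a <- links$left_contig[i]; b <- links$right_contig[i]
    if (!is.null(lg) && a %in% names(lg) && b %in% names(lg) &&
        !is.na(lg[[a]]) && !is.na(lg[[b]]) && lg[[a]] != lg[[b]]) {
      reason[i] <- sprintf("linkage-group conflict (%s vs %s)", lg[[a]], lg[[b]])
      next
    }
    for (co in constraint_orders) {
      pa <- match(a, co); pb <- match(b, co)
      if (!is.na(pa) && !is.na(pb) && abs(pa - pb) != 1L) {
        reason[i] <- "non-adjacent in constraint order"
        break
      }
    }
  }
  ## enforce simple paths: one accepted link per contig side
  used_right <- character(0); used_left <- character(0)
  for (i in seq_len(nrow(links))) {
    if (!is.na(reason[i])) next
    a <- links$left_contig[i]; b <- links$right_contig[i]
    if (a %in% used_left || b %in% used_right) {
      reason[i] <- "contig end already linked"
      next
    }
    used_left <- c(used_left, a); used_right <- c(used_right, b)
  }
  acc <- links[is.na(reason), , drop = FALSE]
  ## cycle check over accepted successor pointers
  succ <- setNames(acc$right_contig, acc$left_contig)
  for (s in names(succ)) {
    seen <- s; cur <- s
    while (!is.na(succ[cur])) {
      cur <- succ[[cur]]
      if (cur %in% seen) stop("cyclic accepted links", call. = FALSE)
      seen <- c(seen, cur)
      if (!(cur %in% names(succ))) break
    }
  }
  rej <- links[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  rownames(acc) <- rownames(rej) <- NULL
  list(accepted = acc, rejected = rej)
}

#' Write ordered contigs into scaffold sequences
#'
#' Joins oriented contig sequences with runs of `gap_length` Ns; `-`
#' oriented contigs are reverse-complemented. The total non-N scaffold
#' length equals the summed contig lengths.
#'
#' @param ordering data frame with `object`, `rank`, `contig_id`,
#'   `orientation` (as from [order_contigs()]).
#' @param contigs named character vector of contig sequences.
#' @param gap_length N-run length between neighbouring contigs.
#' @return list with `scaffolds` (named character vector) and `agp` (layout
#'   data frame compatible with [write_agp()]). Empty ordering gives empty
#'   output with a warning.
#' @export
emit_scaffolds <- function(ordering, contigs, gap_length = 100L) {
  if (nrow(ordering) == 0) {
    warning("empty ordering: no scaffolds emitted")
    return(list(scaffolds = character(0),
                agp = data.frame(object = character(), part_number = integer(),
                                 component_id = character(),
                                 orientation = character(),
                                 component_length = integer(),
                                 gap_length = integer(), stringsAsFactors = FALSE)))
  }
  stopf(!any(duplicated(ordering$contig_id)), "duplicate contig placement: %s",
        paste(unique(ordering$contig_id[duplicated(ordering$contig_id)]),
              collapse = ", "))
  stopf(all(ordering$contig_id %in% names(contigs)),
        "ordering references unknown contigs")
  scaffolds <- character(0); agp <- list()
  gap_run <- strrep("N", gap_length)
  for (obj in unique(ordering$object)) {
    rows <- ordering[ordering$object == obj, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    seqs <- contigs[rows$contig_id]
    flip <- rows$orientation == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    scaffolds[[obj]] <- paste(seqs, collapse = gap_run)
    agp[[obj]] <- data.frame(object = obj, part_number = seq_len(nrow(rows)),
                             component_id = rows$contig_id,
                             orientation = rows$orientation,
                             component_length = nchar(seqs),
                             gap_length = c(rep(gap_length, nrow(rows) - 1L), 0L),
                             stringsAsFactors = FALSE)
  }
  list(scaffolds = scaffolds, agp = do.call(rbind, unname(agp)))
}
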