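## Brute-force oracles, independent of the package implementations they
## check, plus small shared utilities for truth-based comparisons.

## Nx/Lx by explicit sort-cumulate-scan.
oracle_nx <- function(lengths, x = 50) {
  lens <- sort(lengths, decreasing = TRUE)
  total <- sum(lens)
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc >= total * x / 100) return(c(Nx = lens[i], Lx = i))
  }
}

## Exact monomer occurrences by naive sliding substring comparison.
oracle_scan <- function(sequence, monomer) {
  m <- nchar(monomer)
  n <- nchar(sequence)
  if (n < m) return(integer(0))
  starts <- 0:(n - m)
  starts[substring(sequence, starts + 1, starts + m) == monomer]
}

## Maximum per-position coverage depth of a set of intervals, by explicit
## position tabulation (intervals 0-based half-open, coordinates small).
oracle_max_depth <- function(starts, ends) {
  if (!length(starts)) return(0L)
  cover <- integer(max(ends))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    cover[idx] <- cover[idx] + 1L
  }
  max(cover)
}

## True neighbour adjacencies (with orientations) from a truth layout.
truth_adjacencies <- function(layout) {
  ord <- layout$contig_order
  do.call(rbind, lapply(split(ord, ord$chrom), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(left = d$contig_id[-n], right = d$contig_id[-1],
               left_ori = d$orientation[-n], right_ori = d$orientation[-1],
               stringsAsFactors = FALSE)
  }))
}

## Fraction of true adjacencies present among links, counting a link that
## matches in reverse-complement order as recovered.
adjacency_recovery <- function(links, truth_adj) {
  flip <- function(o) ifelse(o == "+", "-", "+")
  key <- function(l, r, lo, ro) paste(l, r, lo, ro)
  fwd <- key(links$left_contig, links$right_contig,
             links$left_orientation, links$right_orientation)
  rev <- key(links$right_contig, links$left_contig,
             flip(links$right_orientation), flip(links$left_orientation))
  mean(key(truth_adj$left, truth_adj$right,
           truth_adj$left_ori, truth_adj$right_ori) %in% c(fwd, rev))
}

## Layout (object/rank/contig/orientation) straight from a truth layout.
layout_from_truth <- function(layout) {
  ord <- layout$contig_order
  data.frame(object = ord$chrom, rank = ord$rank, contig_id = ord$contig_id,
             orientation = ord$orientation, stringsAsFactors = FALSE)
}

## Random ACGT string helper for constructing fixtures in tests.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
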