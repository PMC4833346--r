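mk_aln <- function(q, qs, qe, t, ts, te, strand = "+", score = NULL,
                   identity = 100) {
  data.frame(query_id = q, query_start = qs, query_end = qe, target_id = t,
             target_start = ts, target_end = te, strand = strand,
             identity = identity, length = qe - qs,
             score = if (is.null(score)) qe - qs else score,
             stringsAsFactors = FALSE)
}

test_that("1:1 filtering keeps the dominant alignment and caps depth at 1", {
  dup <- rbind(mk_aln("q", 0, 1000, "t", 0, 1000, score = 100),
               mk_aln("q", 0, 1000, "t", 0, 1000, score = 90))
  kept <- filter_one_to_one(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 100)

  disjoint <- rbind(mk_aln("q", 0, 1000, "t", 0, 1000),
                    mk_aln("q", 2000, 3000, "t", 2000, 3000))
  expect_equal(nrow(filter_one_to_one(disjoint)), 2)

  ## random overlapping staircases: brute-force depth check on both sides
  set.seed(51)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    s <- sample(0:800, n, replace = TRUE)
    len <- sample(150:400, n, replace = TRUE)
    aln <- mk_aln("q", s, s + len, "t",
                  s + sample(0:40, n, replace = TRUE),
                  s + len + sample(0:40, n, replace = TRUE),
                  score = runif(n, 1, 100))
    aln <- aln[aln$target_end > aln$target_start, ]
    out <- filter_one_to_one(aln, min_keep = 10)
    if (nrow(out)) {
      expect_lte(oracle_max_depth(out$query_start, out$query_end), 1L)
      expect_lte(oracle_max_depth(out$target_start, out$target_end), 1L)
    }
  }
})

test_that("small end overlaps are trimmed rather than dropping the alignment", {
  aln <- rbind(mk_aln("a", 0, 10000, "t", 0, 10000, score = 200),
               mk_aln("b", 0, 10000, "t", 9800, 19800, score = 100))
  out <- filter_one_to_one(aln)
  expect_equal(nrow(out), 2)
  b <- out[out$query_id == "b", ]
  expect_equal(b$target_start, 10000)   # 200 bp trimmed off the head
  expect_equal(b$query_start, 200)
})

test_that("chaining builds blocks respecting orientation and the 6 kb boundary", {
  one <- mk_aln("q", 0, 10000, "t", 5000, 15000)
  b <- build_blocks(one)
  expect_equal(nrow(b), 1)
  expect_equal(b$span_length, 10000)

  ## exactly 6000 retained, 5999 removed (strict <)
  boundary <- rbind(mk_aln("q1", 0, 6000, "t", 0, 6000),
                    mk_aln("q2", 0, 5999, "t", 100000, 105999))
  bb <- build_blocks(boundary)
  expect_equal(bb$query_id, "q1")

  ## a planted inversion splits one chromosome into + / - / + blocks
  g <- simulate_diploid(1, 1e6, het_rate = 0, seed = 52)
  f <- fragment_assembly(g, 0, seed = 53)      # single chromosome contig
  r <- mutate_reference(g, n_inversions = 1, divergence = 0,
                        inv_length = 250000, seed = 54)
  aln <- simulate_alignments(f$layout, r$block_map, chunk_size = 10000)
  blocks <- build_blocks(filter_one_to_one(aln))
  expect_equal(nrow(blocks), 3)
  expect_equal(sum(blocks$orientation == "-"), 1)
  minus <- blocks[blocks$orientation == "-", ]
  expect_equal(minus$span_length, 250000)
})

test_that("pass-2 rechaining merges across a removed spurious block", {
  ## collinear run interrupted by a short opposite-strand alignment
  aln <- rbind(mk_aln("q", 0, 20000, "t", 0, 20000),
               mk_aln("q", 20000, 23000, "t", 20000, 23000, strand = "-"),
               mk_aln("q", 23000, 43000, "t", 23000, 43000))
  blocks <- build_blocks(aln, min_block = 6000, max_gap = 50000)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$query_start, 0)
  expect_equal(blocks$query_end, 43000)
})

test_that("blocks are non-overlapping on the query", {
  g <- simulate_diploid(2, 2e5, het_rate = 0, seed = 55)
  f <- fragment_assembly(g, 4, seed = 56)
  ## an inversion guarantees contigs spanning a breakpoint carry >1 block
  r <- mutate_reference(g, n_inversions = 1, inv_length = 50000,
                        divergence = 0.02, seed = 57)
  aln <- simulate_alignments(f$layout, r$block_map, chunk_size = 5000,
                             identity = 98)
  blocks <- build_blocks(filter_one_to_one(aln))
  expect_gt(nrow(blocks), 0)
  expect_gt(max(table(blocks$query_id)), 1)
  for (q in unique(blocks$query_id)) {
    b <- blocks[blocks$query_id == q, ]
    b <- b[order(b$query_start), ]
    if (nrow(b) > 1) expect_true(all(b$query_start[-1] >= b$query_end[-nrow(b)]))
  }
})

test_that("block statistics report coverage, N50 and threshold-gated inversions", {
  whole <- mk_aln("chr1", 0, 1e6, "t", 0, 1e6)
  bs <- block_stats(build_blocks(whole), c(chr1 = 1e6))
  expect_equal(bs$coverage, 1)
  expect_equal(bs$block_n50, 1e6)
  expect_equal(bs$rearrangements, 0)

  ## 150 kb inversion below the 200 kb census threshold is not counted
  g <- simulate_diploid(1, 1e6, het_rate = 0, seed = 58)
  f <- fragment_assembly(g, 0, seed = 59)
  r <- mutate_reference(g, n_inversions = 1, divergence = 0,
                        inv_length = 150000, seed = 60)
  aln <- simulate_alignments(f$layout, r$block_map, chunk_size = 10000)
  blocks <- build_blocks(filter_one_to_one(aln))
  bs2 <- block_stats(blocks, f$contigs)
  expect_equal(bs2$rearrangements, 0)
  bs3 <- block_stats(blocks, f$contigs, rearrangement_min = 100000)
  expect_equal(bs3$rearrangements, 1)
})

test_that("contig ordering recovers the truth and reports ambiguity", {
  g <- simulate_diploid(4, 2e5, het_rate = 0, seed = 61)
  f <- fragment_assembly(g, 9, flip_prob = 0.3, seed = 62)
  r <- mutate_reference(g, divergence = 0.01, seed = 63)
  aln <- simulate_alignments(f$layout, r$block_map, chunk_size = 10000,
                             identity = 99)
  oc <- order_contigs(build_blocks(filter_one_to_one(aln)))
  truth <- f$layout$contig_order
  expect_equal(nrow(oc$ordering), nrow(truth))
  for (ch in unique(truth$chrom)) {
    tr <- truth[truth$chrom == ch, ]
    tr <- tr[order(tr$rank), ]
    got <- oc$ordering[oc$ordering$object == ch, ]
    got <- got[order(got$rank), ]
    expect_equal(got$contig_id, tr$contig_id)
    expect_equal(got$orientation, tr$orientation)
  }

  ## a contig split 60/40 across chromosomes stays unplaced
  amb <- rbind(mk_aln("ctgA", 0, 12000, "chrX", 0, 12000),
               mk_aln("ctgA", 12000, 20000, "chrY", 0, 8000))
  oc2 <- order_contigs(amb_blocks <- build_blocks(amb))
  expect_equal(oc2$unplaced$contig_id, "ctgA")

  single <- build_blocks(mk_aln("lone", 0, 10000, "chrZ", 0, 10000))
  oc3 <- order_contigs(single)
  expect_equal(oc3$ordering$contig_id, "lone")
})

test_that("link reconciliation enforces constraint adjacency and LG agreement", {
  links <- data.frame(left_contig = c("A", "A", "X"),
                      left_orientation = "+",
                      right_contig = c("B", "C", "Y"),
                      right_orientation = "+",
                      evidence = "synteny", object = "chr1",
                      stringsAsFactors = FALSE)
  lg <- data.frame(target_id = c("X", "Y"), assigned_lg = c("LG3", "LG7"),
                   stringsAsFactors = FALSE)
  rec <- reconcile_links(links, constraint_orders = list(c("A", "B", "C")),
                         lg_assignments = lg)
  expect_equal(rec$accepted$right_contig, "B")       # A-B adjacent: kept
  expect_equal(nrow(rec$rejected), 2)
  expect_match(rec$rejected$reason[rec$rejected$right_contig == "C"],
               "non-adjacent")
  expect_match(rec$rejected$reason[rec$rejected$left_contig == "X"],
               "linkage-group")

  cyc <- data.frame(left_contig = c("A", "B", "C"), left_orientation = "+",
                    right_contig = c("B", "C", "A"), right_orientation = "+",
                    evidence = "synteny", object = "chr1",
                    stringsAsFactors = FALSE)
  expect_error(reconcile_links(cyc), "cyclic")
})

test_that("scaffold emission conserves sequence and round-trips orientation", {
  set.seed(64)
  c1 <- rand_dna(10000); c2 <- rand_dna(10000)
  ordering <- data.frame(object = "sc1", rank = 1:2,
                         contig_id = c("c1", "c2"),
                         orientation = c("+", "-"), stringsAsFactors = FALSE)
  out <- emit_scaffolds(ordering, c(c1 = c1, c2 = c2), gap_length = 100)
  expect_equal(nchar(out$scaffolds[["sc1"]]), 20100)
  ## non-N content conserved; '-' contig reverse-complemented in place
  expect_identical(substring(out$scaffolds[["sc1"]], 1, 10000), c1)
  expect_identical(substring(out$scaffolds[["sc1"]], 10101, 20100), revcomp(c2))

  expect_warning(empty <- emit_scaffolds(ordering[0, ], c(c1 = c1)), "empty")
  expect_length(empty$scaffolds, 0)

  dup <- rbind(ordering, ordering[1, ])
  expect_error(emit_scaffolds(dup, c(c1 = c1, c2 = c2)), "duplicate")
})
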