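test_that("diploid simulation hits its heterozygosity target and is seeded", {
  g0 <- simulate_diploid(1, 1e5, het_rate = 0, seed = 1)
  expect_identical(g0$haplotype_a, g0$haplotype_b)
  expect_equal(nrow(g0$truth_snps), 0)

  g <- simulate_diploid(1, 1e6, het_rate = 0.004, seed = 1)
  expected <- 1e6 * 0.004
  tol <- 3 * sqrt(expected * 0.996)
  expect_lt(abs(nrow(g$truth_snps) - expected), tol)
  ## SNPs really differ between haplotypes at recorded positions
  idx <- g$truth_snps$pos[1:50] + 1
  a <- strsplit(g$haplotype_a[["chr1"]], "")[[1]][idx]
  b <- strsplit(g$haplotype_b[["chr1"]], "")[[1]][idx]
  expect_true(all(a != b))
  expect_equal(a, g$truth_snps$allele_a[1:50])

  g2 <- simulate_diploid(1, 1e6, het_rate = 0.004, seed = 1)
  expect_identical(g$haplotype_a, g2$haplotype_a)
  g3 <- simulate_diploid(1, 1e6, het_rate = 0.004, seed = 2)
  expect_false(identical(g$haplotype_a, g3$haplotype_a))
})

test_that("planted tandem arrays appear verbatim and reject bad coordinates", {
  rs <- data.frame(chrom = "chr1", start = 1000L, monomer = "TTAGGG",
                   copies = 100L)
  g <- simulate_diploid(1, 1e4, het_rate = 0.004, repeat_spec = rs, seed = 3)
  expect_identical(substring(g$haplotype_a[["chr1"]], 1001, 1600),
                   strrep("TTAGGG", 100))
  ## SNPs avoid arrays, so both haplotypes carry the array
  expect_identical(substring(g$haplotype_b[["chr1"]], 1001, 1600),
                   strrep("TTAGGG", 100))
  bad <- data.frame(chrom = "chr1", start = 9900L, monomer = "TTAGGG",
                    copies = 100L)
  expect_error(simulate_diploid(1, 1e4, repeat_spec = bad, seed = 3),
               "exceeds chromosome length")
})

test_that("SNP spacing flag enforces a minimum distance", {
  g <- simulate_diploid(1, 2e5, het_rate = 0.01, seed = 4, min_snp_spacing = 21)
  expect_true(all(diff(g$truth_snps$pos) >= 21))
})

test_that("read simulation respects coverage accounting and error-free mode", {
  g <- simulate_diploid(1, 1e5, het_rate = 0, seed = 1)
  expect_equal(nrow(simulate_reads(g, 0, seed = 1)), 0)

  r <- simulate_reads(g, 36, read_length = 100, error_rate = 0, seed = 2)
  total <- sum(nchar(r$sequence))
  expect_gte(total, 3.564e6)   # within 1% of 36x * 100 kb
  expect_lte(total, 3.636e6)
  ## error-free homozygous reads are exact substrings at their truth window
  sub <- r[1:100, ]
  expect_identical(sub$sequence,
                   unname(substring(g$haplotype_a[sub$chrom], sub$start + 1,
                                    sub$start + 100)))
  expect_error(simulate_reads(g, 1, read_length = 2e5, seed = 1),
               "read_length")
})

test_that("read errors land at the requested rate", {
  g <- simulate_diploid(1, 2e5, het_rate = 0, seed = 5)
  r <- simulate_reads(g, 10, read_length = 100, error_rate = 0.01, seed = 6)
  mism <- sum(r$sequence != substring(g$haplotype_a[r$chrom], r$start + 1,
                                      r$start + 100))
  ## expected fraction of reads carrying >= 1 error: 1 - 0.99^100
  p <- 1 - 0.99^100
  expect_lt(abs(mism / nrow(r) - p), 3 * sqrt(p * (1 - p) / nrow(r)))
})

test_that("fragmentation bookkeeping and reconstruction are exact", {
  g <- simulate_diploid(1, 1e5, het_rate = 0, seed = 1)
  f0 <- fragment_assembly(g, 0, seed = 1)
  expect_length(f0$contigs, 1)
  expect_identical(unname(f0$contigs[1]), g$haplotype_a[["chr1"]])

  f <- fragment_assembly(g, 3, overlap_range = c(200, 200), seed = 2)
  expect_length(f$contigs, 4)
  expect_equal(sum(nchar(f$contigs)), 1e5 + 600)
  expect_equal(f$layout$planted_overlaps$overlap_length, rep(200L, 3))

  ## reconstruction across seeds, with and without orientation flips
  for (s in 1:3) {
    ff <- fragment_assembly(g, 5, overlap_range = c(100, 400),
                            flip_prob = 0.5, seed = s)
    rec <- reconstruct_from_layout(ff$contigs, ff$layout)
    expect_identical(rec[["chr1"]], g$haplotype_a[["chr1"]])
  }
  flips <- fragment_assembly(g, 7, flip_prob = 0.5, seed = 9)
  expect_true(any(flips$layout$contig_order$orientation == "-"))
  expect_error(fragment_assembly(g, 50, seed = 1), "too short")
})

test_that("reference mutation produces the stated block map truth", {
  g <- simulate_diploid(2, 1e6, het_rate = 0, seed = 7)
  r0 <- mutate_reference(g, 0, 0, divergence = 0, seed = 1)
  expect_identical(r0$reference, g$haplotype_a)
  expect_equal(nrow(r0$block_map), 2)
  expect_true(all(r0$block_map$orientation == "+"))

  r1 <- mutate_reference(g, n_inversions = 1, divergence = 0,
                         inv_length = 250000, seed = 2)
  bm <- r1$block_map
  minus <- bm[bm$orientation == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$query_end - minus$query_start, 250000)
  ## flanked by + blocks on the same chromosome
  same <- bm[bm$query_id == minus$query_id, ]
  expect_true(all(same$orientation[same$query_end <= minus$query_start] == "+"))
  expect_true(all(same$orientation[same$query_start >= minus$query_end] == "+"))
  ## the planted segment really is reverse-complemented in the reference
  expect_identical(
    substring(r1$reference[[minus$query_id]], minus$target_start + 1,
              minus$target_end),
    revcomp(substring(g$haplotype_a[[minus$query_id]], minus$query_start + 1,
                      minus$query_end)))

  expect_error(mutate_reference(g, n_inversions = 1, inv_length = 5000,
                                seed = 1), ">= 10 kb")
})

test_that("reference divergence matches the requested rate", {
  g <- simulate_diploid(1, 1e6, het_rate = 0, seed = 8)
  r <- mutate_reference(g, divergence = 0.1, seed = 9)
  set.seed(10)
  starts <- sample(0:(1e6 - 1000), 200)
  ident <- vapply(starts, function(s) {
    a <- charToRaw(substring(g$haplotype_a[["chr1"]], s + 1, s + 1000))
    b <- charToRaw(substring(r$reference[["chr1"]], s + 1, s + 1000))
    mean(a == b)
  }, 0)
  expect_lt(abs(mean(ident) - 0.9), 0.01)
})

test_that("translocations swap segments between chromosomes with exact truth", {
  g <- simulate_diploid(2, 5e5, het_rate = 0, seed = 11)
  r <- mutate_reference(g, n_translocations = 1, divergence = 0,
                        trans_length = 50000, seed = 12)
  bm <- r$block_map
  moved <- bm[bm$query_id != bm$target_id, ]
  expect_equal(nrow(moved), 2)   # reciprocal swap: one block each way
  for (i in 1:2) {
    b <- moved[i, ]
    expect_identical(
      substring(r$reference[[b$target_id]], b$target_start + 1, b$target_end),
      substring(g$haplotype_a[[b$query_id]], b$query_start + 1, b$query_end))
  }
})

test_that("simulated markers are contig substrings with conserved counts", {
  g <- simulate_diploid(4, 5e4, het_rate = 0, seed = 13)
  f <- fragment_assembly(g, 2, seed = 14)
  mk <- simulate_markers(f$contigs, f$layout, 100, marker_length = 400,
                         seed = 15)
  expect_length(mk$markers, 100)
  expect_equal(sum(table(mk$truth$linkage_group)), 100)
  for (i in c(1, 50, 100)) {
    tr <- mk$truth[i, ]
    expect_identical(unname(mk$markers[tr$marker_id]),
                     substring(f$contigs[[tr$contig_id]], tr$start + 1, tr$end))
  }
  ## negative controls carry ~15% divergence from their source
  mk2 <- simulate_markers(f$contigs, f$layout, 20, marker_length = 400,
                          n_mutated = 5, seed = 16)
  bad <- mk2$truth[mk2$truth$mutated, ][1, ]
  src <- substring(f$contigs[[bad$contig_id]], bad$start + 1, bad$end)
  mism <- mean(charToRaw(mk2$markers[[bad$marker_id]]) != charToRaw(src))
  expect_gt(mism, 0.10)
  expect_error(simulate_markers(f$contigs, f$layout, 5, marker_length = 1e6,
                                seed = 1), "no contig")
})

test_that("truth-derived alignments project contigs through the block map", {
  g <- simulate_diploid(1, 1e5, het_rate = 0, seed = 17)
  f <- fragment_assembly(g, 3, flip_prob = 0.5, seed = 18)
  r <- mutate_reference(g, divergence = 0, seed = 19)
  aln <- simulate_alignments(f$layout, r$block_map, chunk_size = 8000,
                             identity = 100)
  ## every record: the contig substring (oriented per strand) equals the
  ## reference substring it claims to align to
  for (i in seq_len(nrow(aln))) {
    a <- aln[i, ]
    qs <- substring(f$contigs[[a$query_id]], a$query_start + 1, a$query_end)
    if (a$strand == "-") qs <- revcomp(qs)
    ts <- substring(r$reference[[a$target_id]], a$target_start + 1,
                    a$target_end)
    expect_identical(qs, ts)
  }
})
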