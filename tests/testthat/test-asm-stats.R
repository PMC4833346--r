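test_that("Nx/Lx match hand-worked and brute-force values", {
  expect_equal(nx_stats(c(10, 10, 10), 50), c(Nx = 10, Lx = 2))
  expect_equal(nx_stats(1:10, 50), c(Nx = 7, Lx = 4))
  expect_error(nx_stats(numeric(0)), "empty")

  set.seed(31)
  for (i in 1:100) {
    lens <- sample.int(1e6, sample(1:500, 1), replace = TRUE)
    x <- sample(c(10, 25, 50, 75, 90, 100), 1)
    expect_equal(nx_stats(lens, x), oracle_nx(lens, x))
  }
})

test_that("Nx is permutation-invariant and N100 is the minimum length", {
  set.seed(32)
  lens <- sample.int(1e5, 200)
  expect_equal(nx_stats(lens, 50), nx_stats(sample(lens), 50))
  expect_equal(unname(nx_stats(lens, 100)["Nx"]), min(lens))
})

test_that("GC windows tile, filter on N fraction, and average correctly", {
  two_g <- setNames(strrep("G", 40000), "s1")
  gw <- gc_windows(two_g, window = 20000)
  expect_equal(nrow(gw), 2)
  expect_equal(gw$gc, c(100, 100))

  ## boundary: strictly more than 25% N discarded, exactly 25% retained
  w25 <- setNames(paste0(strrep("N", 25), strrep("G", 75)), "w")
  w26 <- setNames(paste0(strrep("N", 26), strrep("G", 74)), "w")
  expect_equal(nrow(gc_windows(w25, window = 100)), 1)
  expect_warning(out <- gc_windows(w26, window = 100), "discarded")
  expect_equal(nrow(out), 0)

  set.seed(33)
  uniform <- setNames(rand_dna(2e5), "u")
  gw2 <- gc_windows(uniform, window = 20000)
  expect_lt(abs(mean(gw2$gc) - 50), 0.5)
  ## GC computed over non-N bases only
  half_n <- setNames(paste0(strrep("N", 20), strrep("G", 40), strrep("A", 40)),
                     "h")
  gwn <- gc_windows(half_n, window = 100, max_n_fraction = 0.25)
  expect_equal(gwn$gc, 50)
})

test_that("end-pair classification follows the convergent-separation rule", {
  mk <- function(pair, end, tgt, s, e, str) {
    data.frame(pair_id = pair, end = end, target_id = tgt, start = s,
               end_pos = e, strand = str, stringsAsFactors = FALSE)
  }
  ## proper: one target, convergent, 100 kb apart
  proper <- rbind(mk("p", 1, "sc1", 1000, 1800, "+"),
                  mk("p", 2, "sc1", 100200, 101000, "-"))
  res <- classify_end_pairs(proper)
  expect_equal(res$pairs$classification, "same_scaffold_proper")

  ## different targets
  diff_t <- rbind(mk("d", 1, "sc1", 0, 800, "+"),
                  mk("d", 2, "sc2", 0, 800, "-"))
  expect_equal(classify_end_pairs(diff_t)$pairs$classification,
               "different_scaffold")

  ## constructed set: 6 proper, 2 improper, 1 different, 1 orphan
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- mk(paste0("ok", i), 1, "sc1", i * 1000, i * 1000 + 800, "+")
    rows[[length(rows) + 1]] <- mk(paste0("ok", i), 2, "sc1", i * 1000 + 99200, i * 1000 + 100000, "-")
  }
  rows[[length(rows) + 1]] <- mk("bad1", 1, "sc1", 0, 800, "+")      # too close
  rows[[length(rows) + 1]] <- mk("bad1", 2, "sc1", 2000, 2800, "-")
  rows[[length(rows) + 1]] <- mk("bad2", 1, "sc1", 0, 800, "+")      # same strand
  rows[[length(rows) + 1]] <- mk("bad2", 2, "sc1", 99200, 100000, "+")
  rows[[length(rows) + 1]] <- mk("df", 1, "sc1", 0, 800, "+")
  rows[[length(rows) + 1]] <- mk("df", 2, "sc3", 0, 800, "-")
  rows[[length(rows) + 1]] <- mk("or", 1, "sc1", 0, 800, "+")
  res <- classify_end_pairs(do.call(rbind, rows))
  fr <- setNames(res$summary$fraction, res$summary$classification)
  expect_equal(unname(fr["same_scaffold_proper"]), 0.6)
  expect_equal(unname(fr["same_scaffold_improper"]), 0.2)
  expect_equal(unname(fr["different_scaffold"]), 0.1)
  expect_equal(unname(fr["orphan"]), 0.1)
  expect_equal(sum(res$summary$count), 10)
  expect_equal(sum(res$summary$fraction), 1)

  dup <- rbind(mk("x", 1, "sc1", 0, 800, "+"), mk("x", 1, "sc1", 0, 800, "+"))
  expect_error(classify_end_pairs(dup), "duplicate")
})

test_that("separation is measured between outermost aligned coordinates", {
  mk <- function(pair, end, tgt, s, e, str) {
    data.frame(pair_id = pair, end = end, target_id = tgt, start = s,
               end_pos = e, strand = str, stringsAsFactors = FALSE)
  }
  ## outermost span exactly d_min
  at_min <- rbind(mk("m", 1, "t", 0, 800, "+"),
                  mk("m", 2, "t", 49200, 50000, "-"))
  expect_equal(classify_end_pairs(at_min)$pairs$classification,
               "same_scaffold_proper")
  ## one base under d_min
  under <- rbind(mk("u", 1, "t", 1, 800, "+"),
                 mk("u", 2, "t", 49200, 50000, "-"))
  expect_equal(classify_end_pairs(under)$pairs$classification,
               "same_scaffold_improper")
})
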