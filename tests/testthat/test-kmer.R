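test_that("canonical counting collapses reverse complements and skips N", {
  h <- count_kmers("AAAA", 3)
  expect_equal(h$multiplicity, 2L)
  expect_equal(h$count, 1)

  h2 <- count_kmers(c("ACG", "CGT"), 3)   # CGT is revcomp(ACG)
  expect_equal(h2$multiplicity, 2L)
  expect_equal(h2$count, 1)

  h3 <- count_kmers("ACGNACG", 3)          # N-containing k-mers skipped
  expect_equal(h3$multiplicity, 2L)
  expect_equal(h3$count, 1)

  h4 <- count_kmers(character(0), 21)
  expect_equal(h4$total_distinct, 0)
  expect_equal(length(h4$multiplicity), 0L)

  expect_error(count_kmers("ACGT", 4), "odd")
  expect_error(count_kmers("ACGT", 33), "between")
})

test_that("histogram invariants hold on a simulated homozygous spectrum", {
  g <- simulate_diploid(1, 1e5, het_rate = 0, seed = 21)
  r <- simulate_reads(g, 30, read_length = 1000, error_rate = 0, seed = 22)
  h <- count_kmers(r, 21)
  expect_equal(h$total_kmers, sum(h$multiplicity * h$count))
  expect_equal(h$total_distinct, sum(h$count))
  mode <- h$multiplicity[which.max(h$count)]
  expect_gte(mode, 25)
  expect_lte(mode, 35)
})

test_that("mixture fit recovers parameters of model-generated spectra", {
  x <- 1:200
  y <- 1e5 * dnbinom(x, mu = 36.6, size = 10) +
    5e5 * dnbinom(x, mu = 73.2, size = 10)
  fit <- fit_mixture(kmer_histogram(x, y, 21))
  expect_lt(abs(fit$mu - 36.6) / 36.6, 0.01)
  ## component sums within 2% of the generator's component masses
  s <- component_sums(fit, kmer_histogram(x, y, 21))
  expect_lt(abs(s[["H"]] - 1e5) / 1e5, 0.02)
  expect_lt(abs(s[["D"]] - 5e5) / 5e5, 0.02)
})

test_that("a fully homozygous spectrum collapses to the homozygous component", {
  x <- 1:200
  y <- 5e5 * dnbinom(x, mu = 60, size = 15)
  fit <- fit_mixture(kmer_histogram(x, y, 21))
  expect_true(fit$degenerate)
  expect_equal(fit$s1, 0)
  expect_lt(abs(2 * fit$mu - 60) / 60, 0.01)   # homozygous peak at 2*mu
  expect_equal(fit$het_kmers, 0)
})

test_that("fit residual is no worse than the generating parameters on noisy data", {
  x <- 3:150
  set.seed(23)
  clean <- 2e5 * dnbinom(x, mu = 30, size = 20) +
    8e5 * dnbinom(x, mu = 60, size = 20)
  y <- pmax(clean + rnorm(length(x), 0, 20), 0)
  hist <- kmer_histogram(x, y, 21)
  fit <- fit_mixture(hist, fit_cutoff = 3, max_x = 150)
  rss_truth <- sum((y - clean)^2)
  expect_lte(fit$residual_ss, rss_truth * 1.001)
})

test_that("scaling the spectrum scales s1/s2 and leaves mu and rate fixed", {
  x <- 1:200
  y <- 1e5 * dnbinom(x, mu = 36.6, size = 10) +
    5e5 * dnbinom(x, mu = 73.2, size = 10)
  f1 <- fit_mixture(kmer_histogram(x, y, 21))
  f2 <- fit_mixture(kmer_histogram(x, 10 * y, 21))
  expect_lt(abs(f2$mu - f1$mu) / f1$mu, 1e-4)
  expect_lt(abs(f2$s1 / f1$s1 - 10) / 10, 1e-3)
  expect_lt(abs(f2$s2 / f1$s2 - 10) / 10, 1e-3)
  expect_lt(abs(heterozygosity(f2)$rate - heterozygosity(f1)$rate) /
              heterozygosity(f1)$rate, 1e-3)
})

test_that("heterozygosity follows the het/homo k-mer formula exactly", {
  est <- heterozygosity(96126339, 491559122, 21)
  expect_gte(est$rate, 0.004)
  expect_lte(est$rate, 0.005)
  expect_equal(signif(est$rate, 4), 0.004241)
  expect_equal(floor(est$genome_size_nonrep), 539622291)
  ## exact identity, not just a band
  expect_equal(est$rate, (96126339 / 42) / (96126339 / 2 + 491559122))

  expect_equal(heterozygosity(0, 100, 21)$rate, 0)
  expect_error(heterozygosity(0, 0, 21), "undefined")
})

test_that("heterozygosity is monotone in H and antitone in D", {
  H <- seq(1e6, 9e6, length.out = 9)
  r_h <- vapply(H, function(h) heterozygosity(h, 5e8, 21)$rate, 0)
  expect_true(all(diff(r_h) > 0))
  D <- seq(1e8, 9e8, length.out = 9)
  r_d <- vapply(D, function(d) heterozygosity(5e6, d, 21)$rate, 0)
  expect_true(all(diff(r_d) < 0))
})

test_that("genome size estimators recover a simulated 1 Mb diploid", {
  g <- simulate_diploid(1, 1e6, het_rate = 0.004, seed = 24)
  r <- simulate_reads(g, 36, read_length = 100, error_rate = 0.005, seed = 25)
  h <- count_kmers(r, 21)
  fit <- fit_mixture(h)
  gs <- genome_size(fit, h)
  expect_lt(abs(gs[["total_size_estimate"]] - 1e6) / 1e6, 0.05)
  expect_lt(abs(gs[["nonrepetitive_size"]] - 1e6) / 1e6, 0.10)
  ## het estimate in the right range too
  expect_lt(abs(heterozygosity(fit)$rate - 0.004) / 0.004, 0.25)

  empty <- kmer_histogram(1:2, c(5, 3), 21)
  fit2 <- list(fit_cutoff = 10, max_x = 40, mu = 5, size1 = 5, size2 = 5,
               s1 = 1, s2 = 1)
  class(fit2) <- "mixture_fit"
  expect_error(genome_size(fit2, empty), "no histogram mass")
})

test_that("histogram files round-trip through the two-column table format", {
  h <- kmer_histogram(c(1, 5, 9), c(100, 40, 7), 21)
  path <- tempfile(fileext = ".histo")
  write.table(data.frame(h$multiplicity, h$count), path, sep = " ",
              row.names = FALSE, col.names = FALSE)
  h2 <- read_histogram(path, k = 21)
  expect_equal(h2$multiplicity, h$multiplicity)
  expect_equal(h2$count, h$count)
  expect_equal(h2$total_kmers, h$total_kmers)
})
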