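## K-mer spectrum model: canonical k-mer counting, a two-component
## negative-binomial mixture fitted to the multiplicity spectrum, and the
## heterozygosity / genome-size estimators derived from the fitted
## components.
##
## The model for the spectrum K(x) (x = k-mer multiplicity) is
##
##   K(x) = s1 * dnbinom(x, mu = mu,   size = size1)
##        + s2 * dnbinom(x, mu = 2*mu, size = size2)
##
## component 1 holding the heterozygous k-mers (present on one haplotype,
## so at half coverage) and component 2 the homozygous k-mers at full
## coverage. The negative binomial generalizes the Poisson with an
## overdispersion parameter: variance = mean + mean^2/size. The scaling
## factors s1, s2 carry genome size and heterozygosity information.

#' Construct a k-mer multiplicity histogram
#'
#' @param multiplicity integer vector of multiplicities (x >= 1).
#' @param count number of distinct canonical k-mers at each multiplicity.
#' @param k k-mer length the histogram was computed with.
#' @return an object of class `kmer_histogram` with fields `k`,
#'   `multiplicity`, `count`, `total_distinct` (sum of counts) and
#'   `total_kmers` (sum of x * count).
#' @export
kmer_histogram <- function(multiplicity, count, k) {
  stopf(length(multiplicity) == length(count), "length mismatch")
  stopf(all(count >= 0), "counts must be >= 0")
  stopf(all(multiplicity >= 1), "multiplicities must be >= 1")
  o <- order(multiplicity)
  structure(list(k = as.integer(k),
                 multiplicity = as.integer(multiplicity[o]),
                 count = as.numeric(count[o]),
                 total_distinct = sum(as.numeric(count)),
                 total_kmers = sum(as.numeric(multiplicity) * as.numeric(count))),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram: k=%d, %d multiplicity bins, %.4g distinct k-mers, %.4g total k-mers\n",
              x$k, length(x$multiplicity), x$total_distinct, x$total_kmers))
  invisible(x)
}

#' Count canonical k-mers in a read set
#'
#' A k-mer and its reverse complement are collapsed to the lexicographically
#' smaller (canonical) form; k must be odd so no k-mer is its own reverse
#' complement. k-mers containing a non-ACGT character are skipped.
#'
#' @param reads character vector of sequences, a data frame with a `sequence`
#'   column (as produced by [simulate_reads()]), or a path to a FASTA/FASTQ
#'   file.
#' @param k odd k-mer length, 1--31 (21 is the conventional choice for
#'   genome profiling).
#' @return a `kmer_histogram`. Empty input gives an empty histogram.
#' @export
count_kmers <- function(reads, k = 21L) {
  k <- as.integer(k)
  stopf(k >= 1 && k <= 31, "k must be between 1 and 31")
  stopf(k %% 2L == 1L, "k must be odd (canonical counting)")
  if (is.data.frame(reads)) reads <- reads$sequence
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  m <- .kmer_histogram_cpp(as.character(reads), k)
  kmer_histogram(m[, 1], m[, 2], k = k)
}

## Evaluate the two-component mixture at multiplicities x.
mixture_density <- function(x, mu, size1, size2, s1, s2) {
  s1 * dnbinom(x, mu = mu, size = size1) +
    s2 * dnbinom(x, mu = 2 * mu, size = size2)
}

## Running mean with window 3 (ends kept as-is).
smooth3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  c(y[1], (y[-c(1, 2)] + y[-c(1, n)] + y[-c(n - 1, n)]) / 3, y[n])
}

#' Choose the error-exclusion cutoff of a k-mer spectrum
#'
#' Sequencing errors produce a mass of low-multiplicity k-mers; the fit
#' excludes them by starting at the first local minimum (the trough between
#' the error mass and the genomic peaks) of the window-3 smoothed spectrum,
#' with a floor of 3.
#'
#' @param hist a `kmer_histogram`.
#' @return integer multiplicity cutoff.
#' @export
pick_fit_cutoff <- function(hist) {
  x <- hist$multiplicity; y <- smooth3(hist$count)
  if (length(x) < 3) return(3L)
  amax <- which.max(y)
  for (i in 2:(length(x) - 1)) {
    if (i >= amax) break
    if (y[i] <= y[i - 1] && y[i] <= y[i + 1]) return(max(3L, x[i]))
  }
  3L
}

## Initial mu guess: dominant spectrum peak, halved when a secondary peak
## sits near half its position (homozygous peak dominant, het peak visible)
## or when no heterozygous shoulder exists at all (a diploid spectrum's
## dominant peak is the homozygous one unless proven otherwise is NOT
## assumed: a lone peak is taken at face value here and resolved after the
## fit by component relabelling).
init_mu <- function(hist, cutoff) {
  sel <- hist$multiplicity >= cutoff
  stopf(any(sel), "no histogram mass at or above fit_cutoff")
  x <- hist$multiplicity[sel]; y <- smooth3(hist$count[sel])
  m <- x[which.max(y)]
  half <- which(x >= 0.35 * m & x <= 0.65 * m)
  if (length(half) >= 3) {
    yh <- y[half]
    peak <- which(diff(sign(diff(yh))) == -2) + 1
    if (length(peak) && max(yh[peak]) > 0.05 * max(y)) return(m / 2)
  }
  m
}

#' Fit the two-component negative-binomial mixture to a k-mer spectrum
#'
#' Nonlinear least squares (Levenberg--Marquardt) of the mixture density
#' against the spectrum over multiplicities `fit_cutoff <= x <= max_x`.
#' Component means are constrained to `mu` and `2 * mu`; the upper bound
#' `max_x` (default `4 *` the initial mu guess) keeps repetitive k-mers out
#' of the two-component fit. Up to 5 jittered restarts are attempted on
#' failure.
#'
#' @param hist a `kmer_histogram`.
#' @param fit_cutoff minimum multiplicity included; `NULL` picks the first
#'   local minimum of the smoothed spectrum (floor 3), see
#'   [pick_fit_cutoff()].
#' @param max_x maximum multiplicity included; `NULL` for `4 *` initial mu.
#' @return an object of class `mixture_fit`: `mu`, `size1`, `size2`, `s1`,
#'   `s2`, `fit_cutoff`, `max_x`, `residual_ss`, `het_kmers` (H), `homo_kmers`
#'   (D), `k`, `degenerate` (TRUE when the spectrum collapsed to a single
#'   homozygous component), and the fitted table.
#' @export
fit_mixture <- function(hist, fit_cutoff = NULL, max_x = NULL) {
  stopf(inherits(hist, "kmer_histogram"), "hist must be a kmer_histogram")
  cutoff <- if (is.null(fit_cutoff)) pick_fit_cutoff(hist) else as.integer(fit_cutoff)
  mu0 <- init_mu(hist, cutoff)
  xmax <- if (is.null(max_x)) ceiling(4 * mu0) else as.integer(max_x)
  sel <- hist$multiplicity >= cutoff & hist$multiplicity <= xmax
  stopf(sum(sel) >= 5, "too few spectrum bins in [%d, %d] to fit", cutoff, xmax)
  dat <- data.frame(x = hist$multiplicity[sel], y = hist$count[sel])

  peak_height <- function(m) {
    i <- which.min(abs(dat$x - m))
    max(dat$y[i], 1)
  }
  lower <- c(mu = max(cutoff, 1) + 1e-6, size1 = 0.01, size2 = 0.01, s1 = 0, s2 = 0)
  upper <- c(mu = xmax, size1 = 1e6, size2 = 1e6, s1 = Inf, s2 = Inf)
  make_start <- function(m) {
    list(mu = m, size1 = 5, size2 = 5,
         s1 = peak_height(m) / dnbinom(round(m), mu = m, size = 5),
         s2 = peak_height(2 * m) / dnbinom(round(2 * m), mu = 2 * m, size = 5))
  }
  ## when the two components merge into one hump, the spectrum mode is
  ## neither mu nor 2*mu: try both interpretations of the mode (and the
  ## smoothed-minimum guess) and keep the fit with the smallest residual
  amax <- dat$x[which.max(smooth3(dat$y))]
  cand <- unique(pmax(pmin(c(mu0, amax, amax / 2), xmax * 0.9),
                      lower[["mu"]] * 1.01))
  ## deterministic jitter schedule; no RNG so refits are reproducible
  jitters <- list(c(1, 1, 1, 1, 1), c(0.5, 1, 1, 1, 1), c(2, 1, 1, 1, 1),
                  c(1, 0.2, 0.2, 1, 1), c(0.8, 2, 2, 0.5, 0.5),
                  c(1.25, 0.5, 0.5, 2, 2))
  fit <- NULL; best_rss <- Inf; last_res <- NA_real_; n_attempts <- 0L
  for (m in cand) {
    start0 <- make_start(m)
    for (jit in jitters) {
      n_attempts <- n_attempts + 1L
      start <- Map(function(v, j) v * j, start0, as.list(jit))
      start$mu <- min(max(start$mu, lower[["mu"]] * 1.01), xmax * 0.9)
      res <- try(minpack.lm::nlsLM(
        y ~ s1 * dnbinom(x, mu = mu, size = size1) +
          s2 * dnbinom(x, mu = 2 * mu, size = size2),
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                             ptol = 1e-8)), silent = TRUE)
      if (!inherits(res, "try-error")) {
        rss <- sum(residuals(res)^2)
        last_res <- rss
        if (rss < best_rss) { fit <- res; best_rss <- rss }
        break                  # unjittered (or first working) start sufficed
      }
    }
  }
  if (is.null(fit)) {
    stop(sprintf("mixture fit failed to converge after %d attempts (last residual SS: %g)",
                 n_attempts, last_res), call. = FALSE)
  }
  p <- as.list(coef(fit))

  ## parsimony fallback: when a homozygous-only model (s1 = 0) explains the
  ## spectrum essentially as well as the two-component model, prefer it --
  ## a lone peak carries no evidence of a heterozygous component
  single <- try(minpack.lm::nlsLM(
    y ~ s2 * dnbinom(x, mu = m2, size = size2),
    data = dat,
    start = list(m2 = amax, size2 = 5,
                 s2 = peak_height(amax) / dnbinom(round(amax), mu = amax, size = 5)),
    lower = c(m2 = 2 * lower[["mu"]], size2 = 0.01, s2 = 0),
    upper = c(m2 = 2 * xmax, size2 = 1e6, s2 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                         ptol = 1e-8)), silent = TRUE)
  force_single <- FALSE
  if (!inherits(single, "try-error")) {
    rss1 <- sum(residuals(single)^2)
    if (rss1 <= 1.05 * best_rss) {
      q <- as.list(coef(single))
      p <- list(mu = q$m2 / 2, size1 = q$size2, size2 = q$size2,
                s1 = 0, s2 = q$s2)
      force_single <- TRUE
    }
  }

  ## Degenerate single-peak spectra: if everything landed in component 1,
  ## relabel it as the homozygous component at half the fitted mean -- in a
  ## diploid spectrum a lone peak is the homozygous peak (heterozygous mass
  ## cannot exist without homozygous mass, the converse can).
  degenerate <- force_single
  if (p$s1 > 0 && p$s2 / max(p$s1, 1e-300) < 1e-3) {
    p <- list(mu = p$mu / 2, size1 = p$size1, size2 = p$size1,
              s1 = 0, s2 = p$s1)
    degenerate <- TRUE
  } else if (p$s1 / max(p$s2, 1e-300) < 1e-3) {
    degenerate <- TRUE
  }

  fitted_y <- mixture_density(dat$x, p$mu, p$size1, p$size2, p$s1, p$s2)
  rss <- sum((dat$y - fitted_y)^2)
  H <- sum(p$s1 * dnbinom(dat$x, mu = p$mu, size = p$size1))
  D <- sum(p$s2 * dnbinom(dat$x, mu = 2 * p$mu, size = p$size2))
  structure(list(mu = p$mu, size1 = p$size1, size2 = p$size2,
                 s1 = p$s1, s2 = p$s2,
                 fit_cutoff = cutoff, max_x = xmax,
                 residual_ss = rss, het_kmers = H, homo_kmers = D,
                 k = hist$k, degenerate = degenerate,
                 fitted = data.frame(x = dat$x, observed = dat$y,
                                     fitted = fitted_y)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("mixture_fit: peaks at %.1fx and %.1fx | s1=%.4g s2=%.4g ",
                     "size1=%.3g size2=%.3g\n  fit range [%d, %d], residual SS %.4g",
                     "%s\n  H (het k-mers) = %.0f, D (homo k-mers) = %.0f\n"),
              x$mu, 2 * x$mu, x$s1, x$s2, x$size1, x$size2,
              x$fit_cutoff, x$max_x, x$residual_ss,
              if (x$degenerate) " [degenerate: single component]" else "",
              x$het_kmers, x$homo_kmers))
  invisible(x)
}

#' Sum the fitted heterozygous and homozygous component densities
#'
#' @param fit a `mixture_fit`.
#' @param hist the `kmer_histogram` the fit was computed from (defines the
#'   summation range together with the fit's cutoffs).
#' @return named numeric vector `c(H = ..., D = ...)`: the estimated numbers
#'   of non-repetitive heterozygous and homozygous k-mers.
#' @export
component_sums <- function(fit, hist) {
  x <- hist$multiplicity[hist$multiplicity >= fit$fit_cutoff &
                           hist$multiplicity <= fit$max_x]
  c(H = sum(fit$s1 * dnbinom(x, mu = fit$mu, size = fit$size1)),
    D = sum(fit$s2 * dnbinom(x, mu = 2 * fit$mu, size = fit$size2)))
}

#' Per-base heterozygosity from het/homo k-mer sums
#'
#' A heterozygous base contributes k heterozygous k-mers per haplotype, and
#' both het and homo k-mer counts are halved to express haploid content,
#' giving
#'
#'   rate = (H / (2k)) / (H / 2 + D)
#'
#' The denominator `H/2 + D` is the non-repetitive haploid k-mer content,
#' i.e. an estimate of the non-repetitive genome size in bases. SNPs closer
#' than k bases share k-mers, so the rate slightly undercounts tightly
#' clustered heterozygous sites.
#'
#' @param H number of heterozygous k-mers (or a `mixture_fit`, from which H,
#'   D and k are taken).
#' @param D number of homozygous k-mers.
#' @param k k-mer length.
#' @return object of class `het_estimate`: `rate`, `H`, `D`, `k`,
#'   `genome_size_nonrep`.
#' @export
heterozygosity <- function(H, D = NULL, k = NULL) {
  if (inherits(H, "mixture_fit")) {
    fit <- H; H <- fit$het_kmers; D <- fit$homo_kmers; k <- fit$k
  }
  stopf(H >= 0 && D >= 0, "H and D must be >= 0")
  stopf(H > 0 || D > 0, "heterozygosity undefined for H = D = 0")
  stopf(k >= 1, "k must be >= 1")
  denom <- H / 2 + D
  structure(list(rate = (H / (2 * k)) / denom,
                 H = H, D = D, k = k,
                 genome_size_nonrep = denom),
            class = "het_estimate")
}

#' @export
print.het_estimate <- function(x, ...) {
  cat(sprintf("het_estimate: rate = %.6f (%.3f%%) | H=%.0f D=%.0f k=%d | non-repetitive size %.4g bp\n",
              x$rate, 100 * x$rate, x$H, x$D, x$k, x$genome_size_nonrep))
  invisible(x)
}

#' Genome size estimates from a fitted k-mer spectrum
#'
#' Two estimators: the non-repetitive size `H/2 + D` (haploid k-mer content
#' of the two fitted components) and a total size estimate dividing all
#' k-mer mass above the error cutoff by the diploid coverage `2 * mu`.
#'
#' @param fit a `mixture_fit`.
#' @param hist the `kmer_histogram` it was fitted to.
#' @return named numeric vector `c(nonrepetitive_size = ..., total_size_estimate = ...)`
#'   in bases.
#' @export
genome_size <- function(fit, hist) {
  sel <- hist$multiplicity >= fit$fit_cutoff
  stopf(any(sel), "no histogram mass above fit_cutoff")
  mass <- sum(as.numeric(hist$multiplicity[sel]) * hist$count[sel])
  s <- component_sums(fit, hist)
  c(nonrepetitive_size = unname(s["H"] / 2 + s["D"]),
    total_size_estimate = mass / (2 * fit$mu))
}

#' Full k-mer genome profile of a read set
#'
#' Convenience wrapper: count, fit, and derive heterozygosity and genome
#' size in one call.
#'
#' @param reads see [count_kmers()]; alternatively pass `hist` directly.
#' @param k k-mer length.
#' @param hist optional pre-computed `kmer_histogram`.
#' @param fit_cutoff,max_x passed to [fit_mixture()].
#' @return list with `histogram`, `fit`, `het` and `size`.
#' @export
kmer_profile <- function(reads = NULL, k = 21L, hist = NULL,
                         fit_cutoff = NULL, max_x = NULL) {
  if (is.null(hist)) hist <- count_kmers(reads, k)
  fit <- fit_mixture(hist, fit_cutoff = fit_cutoff, max_x = max_x)
  het <- heterozygosity(fit)
  list(histogram = hist, fit = fit, het = het,
       size = genome_size(fit, hist))
}
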