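## Internal sequence helpers. Sequences are plain character strings over ACGT
## (plus N at I/O boundaries); coordinates are 0-based half-open internally.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar or vector over ACGTN.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random ACGT string of length n (uses current RNG stream).
random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute bases at 0-based positions `pos` of string `x` with a random
## different base. Operates on the raw vector for speed.
substitute_bases <- function(x, pos) {
  if (length(pos) == 0L) return(x)
  r <- charToRaw(x)
  ## the three alternatives to each base, indexed by base and a 1..3 draw
  alt <- rbind(charToRaw("CGT"), charToRaw("AGT"),
               charToRaw("ACT"), charToRaw("ACG"))
  base_idx <- match(r[pos + 1L], charToRaw("ACGT"))
  r[pos + 1L] <- alt[cbind(base_idx, sample.int(3L, length(pos), replace = TRUE))]
  rawToChar(r)
}

## Extract substring with 0-based half-open coordinates.
subseq0 <- function(x, start, end) {
  substring(x, start + 1L, end)
}

## Stop unless condition holds, with sprintf-style message.
stopf <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  stopf(is.numeric(seed) && length(seed) == 1L && !is.na(seed),
        "seed must be a single number")
  withr::with_seed(as.integer(seed), expr)
}
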