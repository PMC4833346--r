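## Readers and writers for the formats the pipeline exchanges: FASTA/FASTQ
## (via Biostrings), two-column k-mer histograms, pairwise alignment tables
## (PAF or 12-column BLAST-like), and AGP v2.1 scaffold layouts. Alignments
## are normalized to 0-based half-open coordinates with an explicit strand.

empty_alignments <- function() {
  data.frame(query_id = character(), query_start = integer(),
             query_end = integer(), target_id = character(),
             target_start = integer(), target_end = integer(),
             strand = character(), identity = numeric(),
             length = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write simulated reads to a FASTQ file
#'
#' Qualities are constant ("I", Q40): the simulator models substitution
#' errors, not quality-score realism.
#'
#' @param reads data frame from [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a pairwise alignment table
#'
#' Supports two dialects. `"paf"`: standard PAF, already 0-based half-open,
#' identity derived as `100 * matches / alignment_block_length` and score from
#' the matches column. `"tabular12"`: 12-column BLAST-like tabular output
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) with 1-based inclusive coordinates; a subject
#' interval with end < start denotes a `-` strand hit, per the dialect's
#' convention.
#'
#' @param path file path (tab-separated, no header).
#' @param dialect `"paf"` or `"tabular12"`.
#' @return normalized alignment data frame: `query_id`, `query_start`,
#'   `query_end`, `target_id`, `target_start`, `target_end` (0-based
#'   half-open), `strand`, `identity` (percent), `length`, `score`.
#' @export
read_alignments <- function(path, dialect = c("paf", "tabular12")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- if (dialect == "paf") 12L else 12L
  bad <- which(vapply(fields, length, 0L) < min_cols)
  if (length(bad)) {
    stop(sprintf("malformed %s line %d in %s: expected >= %d columns",
                 dialect, bad[1], path, min_cols), call. = FALSE)
  }
  num <- function(i) as.numeric(vapply(fields, `[[`, "", i))
  chr <- function(i) vapply(fields, `[[`, "", i)
  if (dialect == "paf") {
    strand <- chr(5)
    stopf(all(strand %in% c("+", "-")), "malformed PAF: bad strand column")
    matches <- num(10); blocklen <- num(11)
    out <- data.frame(query_id = chr(1),
                      query_start = as.integer(num(3)),
                      query_end = as.integer(num(4)),
                      target_id = chr(6),
                      target_start = as.integer(num(8)),
                      target_end = as.integer(num(9)),
                      strand = strand,
                      identity = 100 * matches / pmax(blocklen, 1),
                      length = as.integer(blocklen),
                      score = matches,
                      stringsAsFactors = FALSE)
  } else {
    qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
    stopf(all(qs <= qe), "malformed tabular12: query start > end")
    strand <- ifelse(ss <= se, "+", "-")
    ts <- pmin(ss, se); te <- pmax(ss, se)
    out <- data.frame(query_id = chr(1),
                      query_start = as.integer(qs - 1),
                      query_end = as.integer(qe),
                      target_id = chr(2),
                      target_start = as.integer(ts - 1),
                      target_end = as.integer(te),
                      strand = strand,
                      identity = num(3),
                      length = as.integer(num(4)),
                      score = num(12),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$query_end <= out$query_start | out$target_end <= out$target_start)
  if (length(bad)) {
    stop(sprintf("malformed %s line %d in %s: empty interval", dialect, bad[1], path),
         call. = FALSE)
  }
  out
}

#' Write an alignment table in the 12-column tabular dialect
#'
#' Inverse of [read_alignments()] for `dialect = "tabular12"`; coordinates are
#' converted back to 1-based inclusive and `-` strand hits get a descending
#' subject interval.
#'
#' @param aln normalized alignment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  ss <- ifelse(aln$strand == "+", aln$target_start + 1L, aln$target_end)
  se <- ifelse(aln$strand == "+", aln$target_end, aln$target_start + 1L)
  tab <- data.frame(aln$query_id, aln$target_id, aln$identity, aln$length,
                    0L, 0L, aln$query_start + 1L, aln$query_end, ss, se,
                    0, aln$score)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a scaffold layout as AGP v2.1
#'
#' @param layout data frame with columns `object`, `part_number`,
#'   `component_id`, `orientation`, `component_length`, `gap_length`
#'   (one row per contig; a gap row is emitted after every contig except the
#'   last of each object).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  lines <- c("##agp-version\t2.1")
  for (obj in unique(layout$object)) {
    rows <- layout[layout$object == obj, , drop = FALSE]
    pos <- 1L; part <- 1L
    for (i in seq_len(nrow(rows))) {
      len <- rows$component_length[i]
      lines <- c(lines, paste(obj, pos, pos + len - 1L, part, "W",
                              rows$component_id[i], 1L, len,
                              rows$orientation[i], sep = "\t"))
      pos <- pos + len; part <- part + 1L
      if (i < nrow(rows) && rows$gap_length[i] > 0) {
        lines <- c(lines, paste(obj, pos, pos + rows$gap_length[i] - 1L, part,
                                "N", rows$gap_length[i], "scaffold", "yes",
                                "align_genus", sep = "\t"))
        pos <- pos + rows$gap_length[i]; part <- part + 1L
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP file back into a component layout
#'
#' Only `W` (contig) and `N`/`U` (gap) component types are interpreted.
#'
#' @param path AGP file path.
#' @return data frame with columns `object`, `part_number`, `component_id`,
#'   `orientation`, `component_length`, `gap_length` (gap following the
#'   component within its object; 0 for the last).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- list(); gap_pending <- NULL
  for (f in fields) {
    stopf(length(f) >= 8, "malformed AGP line: %s", paste(f, collapse = "\t"))
    if (f[5] == "W") {
      out[[length(out) + 1L]] <- data.frame(
        object = f[1], part_number = as.integer(f[4]),
        component_id = f[6], orientation = f[9],
        component_length = as.integer(f[8]) - as.integer(f[7]) + 1L,
        gap_length = 0L, stringsAsFactors = FALSE)
    } else if (f[5] %in% c("N", "U") && length(out)) {
      out[[length(out)]]$gap_length <- as.integer(f[6])
    }
  }
  if (!length(out)) {
    return(data.frame(object = character(), part_number = integer(),
                      component_id = character(), orientation = character(),
                      component_length = integer(), gap_length = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a two-column k-mer histogram table
#'
#' Accepts the `histo` output convention of common k-mer counters:
#' whitespace-separated `multiplicity count` rows.
#'
#' @param path file path.
#' @param k the k-mer length the histogram was computed with.
#' @return a `kmer_histogram` (see [count_kmers()]).
#' @export
read_histogram <- function(path, k = 21L) {
  tab <- read.table(path, header = FALSE, col.names = c("multiplicity", "count"))
  kmer_histogram(tab$multiplicity, tab$count, k = k)
}
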