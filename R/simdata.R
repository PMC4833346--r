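## Synthetic-data generators: diploid genomes with planted SNPs and tandem
## arrays, sequencing reads, fragmented assemblies with planted end-overlaps,
## rearranged "related reference" genomes with a known block map, and linkage
## markers. All generators are deterministic for a fixed seed and record
## ground truth so downstream modules can be tested without external data.

#' Simulate a diploid genome with planted SNP heterozygosity
#'
#' Generates `n_chrom` random ACGT chromosomes (haplotype A), plants optional
#' tandem repeat arrays, and derives haplotype B by substituting bases at
#' positions drawn binomially at rate `het_rate`. SNPs never fall inside a
#' planted repeat array, so arrays are identical on both haplotypes.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bases (>= 1000). A vector
#'   of per-chromosome lengths is accepted.
#' @param het_rate target per-base heterozygosity, in `[0, 0.05]`.
#' @param repeat_spec optional data frame with columns `chrom`, `start`
#'   (0-based), `monomer`, `copies` describing tandem arrays to plant.
#' @param seed integer seed; identical seeds give identical genomes.
#' @param min_snp_spacing if > 0, successive SNPs on a chromosome are forced
#'   to be at least this many bases apart (thins the binomial draw).
#' @return an object of class `diploid_genome`: a list with `haplotype_a`,
#'   `haplotype_b` (named character vectors), `truth_snps` (data frame of
#'   `chrom`, `pos`, `allele_a`, `allele_b`), `het_rate`, and `repeat_tracks`.
#' @export
simulate_diploid <- function(n_chrom = 1L, chrom_length = 1e6, het_rate = 0.004,
                             repeat_spec = NULL, seed = 1L, min_snp_spacing = 0L) {
  stopf(all(chrom_length >= 1000), "chrom_length must be >= 1 kb")
  stopf(het_rate >= 0 && het_rate <= 0.05, "het_rate must be in [0, 0.05]")
  lens <- as.integer(rep_len(chrom_length, n_chrom))
  chroms <- paste0("chr", seq_len(n_chrom))
  if (!is.null(repeat_spec)) {
    stopf(all(c("chrom", "start", "monomer", "copies") %in% names(repeat_spec)),
          "repeat_spec needs columns chrom, start, monomer, copies")
    arr_len <- nchar(repeat_spec$monomer) * repeat_spec$copies
    idx <- match(repeat_spec$chrom, chroms)
    stopf(!anyNA(idx), "repeat_spec references unknown chromosome")
    stopf(all(repeat_spec$start >= 0 & repeat_spec$start + arr_len <= lens[idx]),
          "planted repeat array exceeds chromosome length")
  }

  with_seed(seed, {
    hap_a <- vapply(lens, random_seq, "")
    names(hap_a) <- chroms

    tracks <- data.frame(chrom = character(), start = integer(),
                         monomer = character(), copies = integer(),
                         stringsAsFactors = FALSE)
    if (!is.null(repeat_spec) && nrow(repeat_spec) > 0) {
      for (i in seq_len(nrow(repeat_spec))) {
        ch <- repeat_spec$chrom[i]
        s <- as.integer(repeat_spec$start[i])
        arr <- strrep(repeat_spec$monomer[i], repeat_spec$copies[i])
        r <- charToRaw(hap_a[[ch]])
        r[(s + 1L):(s + nchar(arr))] <- charToRaw(arr)
        hap_a[[ch]] <- rawToChar(r)
      }
      tracks <- data.frame(chrom = repeat_spec$chrom,
                           start = as.integer(repeat_spec$start),
                           monomer = repeat_spec$monomer,
                           copies = as.integer(repeat_spec$copies),
                           stringsAsFactors = FALSE)
    }

    hap_b <- hap_a
    snps <- vector("list", n_chrom)
    for (i in seq_len(n_chrom)) {
      n_snp <- rbinom(1L, lens[i], het_rate)
      pos <- sort(sample.int(lens[i], n_snp) - 1L)
      if (nrow(tracks) > 0) {
        tr <- tracks[tracks$chrom == chroms[i], , drop = FALSE]
        for (j in seq_len(nrow(tr))) {
          w <- tr$start[j] + nchar(tr$monomer[j]) * tr$copies[j]
          pos <- pos[pos < tr$start[j] | pos >= w]
        }
      }
      if (min_snp_spacing > 0L && length(pos) > 1L) {
        keep <- c(TRUE, diff(pos) >= min_snp_spacing)
        while (!all(keep)) {
          pos <- pos[keep]
          keep <- c(TRUE, diff(pos) >= min_snp_spacing)
        }
      }
      if (length(pos) > 0) {
        a <- rawToChar(charToRaw(hap_a[[i]])[pos + 1L], multiple = TRUE)
        hap_b[[i]] <- substitute_bases(hap_b[[i]], pos)
        b <- rawToChar(charToRaw(hap_b[[i]])[pos + 1L], multiple = TRUE)
        snps[[i]] <- data.frame(chrom = chroms[i], pos = pos,
                                allele_a = a, allele_b = b,
                                stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, snps[!vapply(snps, is.null, TRUE)])
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(), pos = integer(),
                          allele_a = character(), allele_b = character(),
                          stringsAsFactors = FALSE)
    }
    structure(list(haplotype_a = hap_a, haplotype_b = hap_b,
                   truth_snps = truth, het_rate = het_rate,
                   repeat_tracks = tracks),
              class = "diploid_genome")
  })
}

## Resolve a genome argument to a named character vector of chromosome
## sequences (haplotype A for diploid_genome objects).
haploid_seqs <- function(genome) {
  if (inherits(genome, "diploid_genome")) genome$haplotype_a
  else if (is.character(genome) && !is.null(names(genome))) genome
  else stop("genome must be a diploid_genome or a named character vector")
}

#' Simulate whole-genome shotgun reads from a diploid genome
#'
#' Reads of fixed length are sampled uniformly from both haplotypes with equal
#' probability so that the total read bases equal `coverage` times the haploid
#' genome length (within rounding). Substitution errors are applied at
#' `error_rate` per base.
#'
#' @param genome a `diploid_genome` (or named character vector, treated as a
#'   homozygous genome).
#' @param coverage target haploid coverage (x); 0 gives an empty read set.
#' @param read_length read length in bases; must not exceed the shortest
#'   chromosome.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return data frame with columns `read_id`, `sequence`, `haplotype`,
#'   `chrom`, `start` (0-based truth of the sampled window).
#' @export
simulate_reads <- function(genome, coverage, read_length = 100L,
                           error_rate = 0, seed = 1L) {
  stopf(coverage >= 0, "coverage must be >= 0")
  hap_a <- haploid_seqs(genome)
  hap_b <- if (inherits(genome, "diploid_genome")) genome$haplotype_b else hap_a
  lens <- nchar(hap_a)
  stopf(read_length <= min(lens), "read_length exceeds a chromosome length")
  glen <- sum(lens)
  n_reads <- round(coverage * glen / read_length)
  if (n_reads == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      haplotype = character(), chrom = character(),
                      start = integer(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    hap <- sample(c("A", "B"), n_reads, replace = TRUE)
    chrom_idx <- sample.int(length(lens), n_reads, replace = TRUE,
                            prob = lens / glen)
    start <- floor(runif(n_reads) * (lens[chrom_idx] - read_length + 1L))
    seqs <- character(n_reads)
    for (h in c("A", "B")) {
      src <- if (h == "A") hap_a else hap_b
      for (i in seq_along(lens)) {
        sel <- which(hap == h & chrom_idx == i)
        if (length(sel)) {
          seqs[sel] <- substring(src[[i]], start[sel] + 1L,
                                 start[sel] + read_length)
        }
      }
    }
    if (error_rate > 0) {
      big <- paste(seqs, collapse = "")
      n_err <- rbinom(1L, nchar(big), error_rate)
      if (n_err > 0) {
        pos <- sample.int(nchar(big), n_err) - 1L
        big <- substitute_bases(big, pos)
      }
      off <- (seq_len(n_reads) - 1L) * read_length
      seqs <- substring(big, off + 1L, off + read_length)
    }
    data.frame(read_id = sprintf("read_%07d", seq_len(n_reads)),
               sequence = seqs,
               haplotype = hap,
               chrom = names(lens)[chrom_idx],
               start = as.integer(start),
               stringsAsFactors = FALSE)
  })
}

#' Fragment a genome into contigs with planted end-overlaps
#'
#' Each chromosome (haplotype A) is cut at `n_breaks` random positions into
#' `n_breaks + 1` contigs; at every junction the left contig is extended into
#' the right one by an overlap length drawn from `overlap_range`, so
#' neighbouring contigs share an exact end-to-start overlap. Optionally a
#' fraction of contigs is emitted reverse-complemented, recorded as `-`
#' orientation in the truth layout.
#'
#' @param genome `diploid_genome` or named character vector.
#' @param n_breaks breaks per chromosome (>= 0).
#' @param overlap_range length-2 vector, the inclusive range overlaps are
#'   drawn from (use `c(0, 0)` for abutting contigs).
#' @param flip_prob probability that a contig is emitted `-` oriented.
#' @param seed integer seed.
#' @param min_contig minimum contig length; cut positions are drawn so that
#'   no contig is shorter (default 10 kb, the scale below which long-read
#'   assembler contigs are rare and reference-guided placement is
#'   unreliable).
#' @return list with `contigs` (named character vector) and `layout`, a
#'   `truth_layout`: `contig_order` (chrom, rank, contig_id, orientation,
#'   start, end in source coordinates), `planted_overlaps`
#'   (left_contig, right_contig, overlap_length), and `source` sequences.
#' @export
fragment_assembly <- function(genome, n_breaks, overlap_range = c(0L, 0L),
                              flip_prob = 0, seed = 1L, min_contig = 10000L) {
  stopf(n_breaks >= 0, "n_breaks must be >= 0")
  stopf(length(overlap_range) == 2 && overlap_range[1] <= overlap_range[2] &&
          overlap_range[1] >= 0, "overlap_range must be a non-negative range")
  seqs <- haploid_seqs(genome)
  with_seed(seed, {
    orders <- list(); overlaps <- list(); contigs <- list()
    cid <- 0L
    for (ch in names(seqs)) {
      L <- nchar(seqs[[ch]])
      nb <- n_breaks
      ## every contig at least min_contig long (and longer than any planted
      ## overlap): sample cut gaps constructively with a floor
      min_ctg <- max(as.integer(min_contig), overlap_range[2] * 2L + 1L, 2L)
      extra <- L - (nb + 1L) * min_ctg
      stopf(extra >= 0, "chromosome %s too short for %d breaks with min_contig %d",
            ch, n_breaks, min_ctg)
      cuts <- if (nb > 0) {
        raw <- sort(as.integer(floor(runif(nb) * (extra + 1))))
        raw + seq_len(nb) * min_ctg
      } else integer(0)
      ov <- if (nb > 0) {
        as.integer(floor(runif(nb, overlap_range[1], overlap_range[2] + 1)))
      } else integer(0)
      starts <- c(0L, cuts)
      ends <- c(cuts + ov, L)
      ctg_len <- ends - starts
      if (nb > 0) {
        stopf(all(ctg_len[seq_len(nb)] > ov) && all(ctg_len[-1L] > ov),
              "planted overlap longer than a flanking contig")
      }
      ids <- sprintf("ctg_%05d", cid + seq_along(starts))
      cid <- cid + length(starts)
      ori <- ifelse(runif(length(ids)) < flip_prob, "-", "+")
      seq_i <- substring(seqs[[ch]], starts + 1L, ends)
      flip <- ori == "-"
      if (any(flip)) seq_i[flip] <- revcomp(seq_i[flip])
      contigs[[ch]] <- setNames(seq_i, ids)
      orders[[ch]] <- data.frame(chrom = ch, rank = seq_along(ids),
                                 contig_id = ids, orientation = ori,
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
      if (nb > 0) {
        overlaps[[ch]] <- data.frame(left_contig = ids[-length(ids)],
                                     right_contig = ids[-1],
                                     overlap_length = ov,
                                     stringsAsFactors = FALSE)
      }
    }
    layout <- structure(list(
      contig_order = do.call(rbind, unname(orders)),
      planted_overlaps = if (length(overlaps)) do.call(rbind, unname(overlaps))
                         else data.frame(left_contig = character(),
                                         right_contig = character(),
                                         overlap_length = integer(),
                                         stringsAsFactors = FALSE),
      source = seqs), class = "truth_layout")
    list(contigs = unlist(unname(contigs)), layout = layout)
  })
}

#' Reconstruct source chromosomes from a truth layout
#'
#' Trims the planted overlap from each left contig and concatenates contigs in
#' layout order; used as the reconstruction oracle for fragmentation and gap
#' closure.
#'
#' @param contigs named character vector of contig sequences.
#' @param layout a `truth_layout` from [fragment_assembly()].
#' @return named character vector of reconstructed chromosome sequences.
#' @export
reconstruct_from_layout <- function(contigs, layout) {
  ord <- layout$contig_order
  ov <- layout$planted_overlaps
  out <- character(0)
  for (ch in unique(ord$chrom)) {
    rows <- ord[ord$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$rank), , drop = FALSE]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      s <- contigs[[rows$contig_id[i]]]
      if (rows$orientation[i] == "-") s <- revcomp(s)
      if (i < nrow(rows)) {
        o <- ov$overlap_length[ov$left_contig == rows$contig_id[i] &
                                 ov$right_contig == rows$contig_id[i + 1]]
        if (length(o) == 1 && o > 0) s <- subseq0(s, 0L, nchar(s) - o)
      }
      pieces[i] <- s
    }
    out[[ch]] <- paste(pieces, collapse = "")
  }
  out
}

#' Derive a rearranged, diverged reference genome with a known block map
#'
#' Plants non-overlapping inversions (segments reverse-complemented in place)
#' and reciprocal translocations (equal-length segments swapped between two
#' chromosomes), then applies uniform point divergence. The returned block map
#' lists the maximal collinear segments between the source genome (query) and
#' the derived reference (target), with orientation.
#'
#' @param genome `diploid_genome` or named character vector (the query side).
#' @param n_inversions,n_translocations number of events to plant.
#' @param divergence per-base substitution rate applied to the reference.
#' @param inv_length,trans_length segment length(s) for the events (recycled);
#'   all segments must be >= 10 kb.
#' @param seed integer seed.
#' @return list with `reference` (named character vector), `block_map` (data
#'   frame: query_id, query_start, query_end, target_id, target_start,
#'   target_end, orientation), and `divergence`.
#' @export
mutate_reference <- function(genome, n_inversions = 0L, n_translocations = 0L,
                             divergence = 0, inv_length = 250000L,
                             trans_length = 100000L, seed = 1L) {
  seqs <- haploid_seqs(genome)
  inv_len <- as.integer(rep_len(inv_length, max(n_inversions, 1L)))
  tr_len <- as.integer(rep_len(trans_length, max(n_translocations, 1L)))
  stopf(n_inversions == 0 || all(inv_len >= 10000),
        "rearranged segments must be >= 10 kb")
  stopf(n_translocations == 0 || all(tr_len >= 10000),
        "rearranged segments must be >= 10 kb")
  lens <- nchar(seqs)
  with_seed(seed, {
    ## reserved[[chrom]] holds planted segments as (start, end) rows
    reserved <- setNames(rep(list(matrix(integer(0), 0, 2)), length(seqs)),
                         names(seqs))
    place <- function(chrom, len) {
      occ <- reserved[[chrom]]
      for (try in 1:200) {
        s <- floor(runif(1) * (lens[[chrom]] - len + 1L))
        e <- s + len
        if (!nrow(occ) || all(e <= occ[, 1] | s >= occ[, 2])) {
          reserved[[chrom]] <<- rbind(occ, c(s, e))
          return(c(s, e))
        }
      }
      stop("could not place rearranged segments disjointly", call. = FALSE)
    }
    inv <- list(); tra <- list()
    for (i in seq_len(n_inversions)) {
      ch <- sample(names(seqs)[lens >= inv_len[i]], 1L)
      se <- place(ch, inv_len[i])
      inv[[i]] <- list(chrom = ch, start = se[1], end = se[2])
    }
    for (i in seq_len(n_translocations)) {
      stopf(length(seqs) >= 2, "translocations need at least two chromosomes")
      chs <- sample(names(seqs)[lens >= tr_len[i]], 2L)
      se1 <- place(chs[1], tr_len[i]); se2 <- place(chs[2], tr_len[i])
      tra[[i]] <- list(chrom1 = chs[1], start1 = se1[1], end1 = se1[2],
                       chrom2 = chs[2], start2 = se2[1], end2 = se2[2])
    }

    ref <- seqs
    ## segment-level edits: inversions in place, translocations swap content
    for (v in inv) {
      piece <- revcomp(subseq0(ref[[v$chrom]], v$start, v$end))
      r <- charToRaw(ref[[v$chrom]])
      r[(v$start + 1L):v$end] <- charToRaw(piece)
      ref[[v$chrom]] <- rawToChar(r)
    }
    for (v in tra) {
      p1 <- subseq0(ref[[v$chrom1]], v$start1, v$end1)
      p2 <- subseq0(ref[[v$chrom2]], v$start2, v$end2)
      r1 <- charToRaw(ref[[v$chrom1]]); r2 <- charToRaw(ref[[v$chrom2]])
      r1[(v$start1 + 1L):v$end1] <- charToRaw(p2)
      r2[(v$start2 + 1L):v$end2] <- charToRaw(p1)
      ref[[v$chrom1]] <- rawToChar(r1); ref[[v$chrom2]] <- rawToChar(r2)
    }
    if (divergence > 0) {
      for (ch in names(ref)) {
        n_mut <- rbinom(1L, lens[[ch]], divergence)
        if (n_mut > 0) {
          ref[[ch]] <- substitute_bases(ref[[ch]], sample.int(lens[[ch]], n_mut) - 1L)
        }
      }
    }

    ## true block map: breakpoints on the QUERY genome, then map each piece
    blocks <- list()
    for (ch in names(seqs)) {
      bp <- c(0L, lens[[ch]])
      for (v in inv) if (v$chrom == ch) bp <- c(bp, v$start, v$end)
      for (v in tra) {
        if (v$chrom1 == ch) bp <- c(bp, v$start1, v$end1)
        if (v$chrom2 == ch) bp <- c(bp, v$start2, v$end2)
      }
      bp <- sort(unique(bp))
      for (i in seq_len(length(bp) - 1L)) {
        qs <- bp[i]; qe <- bp[i + 1L]
        tgt <- list(id = ch, s = qs, e = qe, ori = "+")
        for (v in inv) {
          if (v$chrom == ch && qs >= v$start && qe <= v$end) tgt$ori <- "-"
        }
        for (v in tra) {
          if (v$chrom1 == ch && qs >= v$start1 && qe <= v$end1) {
            tgt <- list(id = v$chrom2, s = v$start2, e = v$end2, ori = "+")
          } else if (v$chrom2 == ch && qs >= v$start2 && qe <= v$end2) {
            tgt <- list(id = v$chrom1, s = v$start1, e = v$end1, ori = "+")
          }
        }
        blocks[[length(blocks) + 1L]] <-
          data.frame(query_id = ch, query_start = qs, query_end = qe,
                     target_id = tgt$id, target_start = tgt$s,
                     target_end = tgt$e, orientation = tgt$ori,
                     stringsAsFactors = FALSE)
      }
    }
    bm <- do.call(rbind, blocks)
    ## merge consecutive identity pieces that were split only by sorting
    merged <- list()
    for (i in seq_len(nrow(bm))) {
      row <- bm[i, ]
      n <- length(merged)
      if (n > 0) {
        last <- merged[[n]]
        if (last$query_id == row$query_id && last$orientation == "+" &&
            row$orientation == "+" && last$target_id == row$target_id &&
            last$query_end == row$query_start &&
            last$target_end == row$target_start) {
          last$query_end <- row$query_end
          last$target_end <- row$target_end
          merged[[n]] <- last
          next
        }
      }
      merged[[n + 1L]] <- row
    }
    bm <- do.call(rbind, merged)
    rownames(bm) <- NULL
    list(reference = ref, block_map = bm, divergence = divergence)
  })
}

#' Draw linkage-map marker sequences from contig interiors
#'
#' Markers are exact substrings of contigs (which are themselves placed on
#' known source chromosomes = linkage groups in the truth layout). A subset
#' can be emitted as negative controls with a fraction of bases mutated, which
#' downstream identity filters are expected to drop.
#'
#' @param contigs named character vector of contig sequences.
#' @param layout `truth_layout` giving each contig's source chromosome.
#' @param n_markers number of markers to draw.
#' @param marker_length marker length in bases.
#' @param n_mutated number of markers emitted as mutated negative controls.
#' @param mutation_rate per-base substitution rate for negative controls.
#' @param seed integer seed.
#' @return list with `markers` (named character vector) and `truth` (data
#'   frame: marker_id, linkage_group, contig_id, start, end, mutated).
#' @export
simulate_markers <- function(contigs, layout, n_markers, marker_length = 500L,
                             n_mutated = 0L, mutation_rate = 0.15, seed = 1L) {
  ord <- layout$contig_order
  lens <- nchar(contigs)
  eligible <- names(contigs)[lens >= marker_length + 2L]
  stopf(length(eligible) > 0, "no contig can hold a %d bp marker", marker_length)
  stopf(n_mutated <= n_markers, "n_mutated cannot exceed n_markers")
  with_seed(seed, {
    pick <- sample(eligible, n_markers, replace = TRUE,
                   prob = lens[eligible] / sum(lens[eligible]))
    start <- vapply(pick, function(ctg) {
      1L + floor(runif(1) * (lens[[ctg]] - marker_length - 1L))
    }, 0)
    ids <- sprintf("marker_%04d", seq_len(n_markers))
    seqs <- substring(contigs[pick], start + 1L, start + marker_length)
    mutated <- rep(FALSE, n_markers)
    if (n_mutated > 0) {
      sel <- sample.int(n_markers, n_mutated)
      mutated[sel] <- TRUE
      for (i in sel) {
        n_mut <- max(1L, round(marker_length * mutation_rate))
        seqs[i] <- substitute_bases(seqs[i], sample.int(marker_length, n_mut) - 1L)
      }
    }
    lg <- ord$chrom[match(pick, ord$contig_id)]
    list(markers = setNames(seqs, ids),
         truth = data.frame(marker_id = ids, linkage_group = lg,
                            contig_id = unname(pick), start = as.integer(start),
                            end = as.integer(start + marker_length),
                            mutated = mutated, stringsAsFactors = FALSE))
  })
}

#' Synthesize contig-versus-reference alignment records from ground truth
#'
#' Projects each contig of a fragmented assembly through the true block map of
#' a derived reference and emits normalized alignment records (optionally
#' split into chunks, as a local aligner would produce). Used as a
#' deterministic stand-in for external whole-genome alignments when testing
#' the synteny-block and ordering logic.
#'
#' @param layout `truth_layout` from [fragment_assembly()].
#' @param block_map true block map from [mutate_reference()].
#' @param chunk_size maximum alignment record length; longer collinear pieces
#'   are split into consecutive chunks.
#' @param identity percent identity to assign (default `100 * (1 - divergence)`
#'   is up to the caller; plain 100 if NULL and no divergence known).
#' @param min_piece pieces shorter than this are dropped (sub-resolution
#'   fragments an aligner would miss).
#' @return alignment data frame in the package's normalized form (see
#'   [read_alignments()]): query_id, query_start, query_end, target_id,
#'   target_start, target_end, strand, identity, length, score.
#' @export
simulate_alignments <- function(layout, block_map, chunk_size = 10000L,
                                identity = 100, min_piece = 50L) {
  ord <- layout$contig_order
  recs <- list()
  for (i in seq_len(nrow(ord))) {
    ctg <- ord[i, ]
    bm <- block_map[block_map$query_id == ctg$chrom, , drop = FALSE]
    for (j in seq_len(nrow(bm))) {
      b <- bm[j, ]
      x <- max(ctg$start, b$query_start); y <- min(ctg$end, b$query_end)
      if (y - x < min_piece) next
      ## split into chunks along the query genome axis
      cs <- seq(x, y, by = chunk_size)
      if (cs[length(cs)] < y) cs <- c(cs, y)
      for (k in seq_len(length(cs) - 1L)) {
        px <- cs[k]; py <- cs[k + 1L]
        if (py - px < min_piece) next
        ## genomic -> reference coordinates through the block
        if (b$orientation == "+") {
          ts <- b$target_start + (px - b$query_start)
          te <- b$target_start + (py - b$query_start)
        } else {
          ts <- b$target_start + (b$query_end - py)
          te <- b$target_start + (b$query_end - px)
        }
        ## genomic -> contig-local coordinates
        if (ctg$orientation == "+") {
          qs <- px - ctg$start; qe <- py - ctg$start
        } else {
          qs <- ctg$end - py; qe <- ctg$end - px
        }
        strand <- if (ctg$orientation == b$orientation) "+" else "-"
        recs[[length(recs) + 1L]] <- data.frame(
          query_id = ctg$contig_id, query_start = qs, query_end = qe,
          target_id = b$target_id, target_start = ts, target_end = te,
          strand = strand, identity = identity, length = py - px,
          score = (py - px) * identity / 100, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs)) return(empty_alignments())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
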