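## End-to-end demonstration pipeline over simulated data: simulate ->
## profile -> stats -> anchor -> synteny -> scaffold -> gapclose ->
## repeatscan -> chain, each stage writing its outputs and a JSON-lines
## manifest entry. Stage order mirrors the scaffolding layering of the
## method (shared synteny first, then independent map evidence, then
## linkage information).

#' Default pipeline configuration
#'
#' Parameters are grouped per stage; every default matches the module-level
#' documentation. Demonstration scale (a few hundred kb) keeps the full run
#' in seconds.
#'
#' @return nested list of per-stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_chrom = 4L, chrom_length = 200000L, het = 0.004,
                    coverage = 25, read_len = 100L, error = 0.002,
                    breaks = 5L, overlap_min = 200L, overlap_max = 400L,
                    telomere_monomer = "TTAGGG", telomere_copies = 120L),
    profile = list(k = 21L, cutoff = NULL, max_x = NULL),
    stats = list(window = 20000L, max_n = 0.25, dmin = 50000L, dmax = 250000L),
    anchor = list(n_markers = 60L, marker_length = 500L,
                  min_identity = 90, min_coverage = 80, top = 5L),
    synteny = list(divergence = 0.02, min_block = 6000L, max_gap = 50000L,
                   rearr_min = 200000L, chunk = 10000L),
    scaffold = list(gap_n = 100L),
    gapclose = list(min_identity = 95, min_len = 100L, end_window = 10000L),
    repeatscan = list(monomer = "TTAGGG", max_spacer = 100L, min_copies = 3L,
                      window = 10000L),
    chain = list(max_gap = 10000L, n_donor_chroms = 2L, n_reads = 300L)
  )
}

merge_config <- function(defaults, config) {
  for (key in names(config)) {
    stopf(key %in% names(defaults), "unknown config key: %s", key)
    if (is.list(defaults[[key]]) && is.list(config[[key]])) {
      for (sub in names(config[[key]])) {
        stopf(sub %in% names(defaults[[key]]),
              "unknown config key: %s.%s", key, sub)
        defaults[[key]][[sub]] <- config[[key]][[sub]]
      }
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  defaults
}

#' Run the full simulated-data pipeline
#'
#' Executes every stage on a freshly simulated genome, writing stage outputs
#' under `outdir` and appending one JSON line per stage to
#' `manifest.jsonl`. Any stage failure aborts with an error naming the
#' stage. Identical `config` (including `seed`) produces byte-identical
#' outputs.
#'
#' @param config list overriding parts of [default_config()]; unknown keys
#'   are rejected.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("scafkit_run_")) {
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.jsonl")
  if (file.exists(manifest_path)) file.remove(manifest_path)
  note <- function(stage, outputs, info = list()) {
    line <- jsonlite::toJSON(c(list(stage = stage, outputs = as.list(outputs)),
                               info), auto_unbox = TRUE)
    cat(line, "\n", sep = "", file = manifest_path, append = TRUE)
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- list()

  res$simulate <- stage("simulate", {
    p <- cfg$simulate
    rs <- data.frame(chrom = "chr1",
                     start = as.integer(p$chrom_length * 0.6),
                     monomer = p$telomere_monomer,
                     copies = p$telomere_copies)
    genome <- simulate_diploid(p$n_chrom, p$chrom_length, p$het,
                               repeat_spec = rs, seed = cfg$seed)
    reads <- simulate_reads(genome, p$coverage, p$read_len, p$error,
                            seed = cfg$seed + 1L)
    frag <- fragment_assembly(genome, p$breaks,
                              c(p$overlap_min, p$overlap_max),
                              seed = cfg$seed + 2L)
    write_fasta(genome$haplotype_a, file.path(outdir, "genome_hapA.fa"))
    write_fasta(frag$contigs, file.path(outdir, "contigs.fa"))
    write_fastq(reads, file.path(outdir, "reads.fq"))
    write.table(frag$layout$contig_order, file.path(outdir, "truth_layout.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("simulate", c("genome_hapA.fa", "contigs.fa", "reads.fq",
                       "truth_layout.tsv"),
         list(n_reads = nrow(reads), n_contigs = length(frag$contigs)))
    list(genome = genome, reads = reads, frag = frag)
  })

  res$profile <- stage("profile", {
    p <- cfg$profile
    prof <- kmer_profile(res$simulate$reads, k = p$k,
                         fit_cutoff = p$cutoff, max_x = p$max_x)
    tab <- data.frame(multiplicity = prof$histogram$multiplicity,
                      count = prof$histogram$count)
    write.table(tab, file.path(outdir, "kmer_histogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(mu = prof$fit$mu, s1 = prof$fit$s1, s2 = prof$fit$s2,
           size1 = prof$fit$size1, size2 = prof$fit$size2,
           heterozygosity = prof$het$rate,
           genome_size_nonrepetitive = unname(prof$size["nonrepetitive_size"]),
           genome_size_total = unname(prof$size["total_size_estimate"]),
           degenerate = prof$fit$degenerate),
      file.path(outdir, "kmer_fit.json"), auto_unbox = TRUE, digits = NA)
    note("profile", c("kmer_histogram.tsv", "kmer_fit.json"),
         list(mu = prof$fit$mu, heterozygosity = prof$het$rate))
    prof
  })

  res$stats <- stage("stats", {
    p <- cfg$stats
    contigs <- res$simulate$frag$contigs
    st <- assembly_stats(contigs)
    gc <- gc_windows(contigs, window = p$window, max_n_fraction = p$max_n)
    write.table(st, file.path(outdir, "assembly_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gc, file.path(outdir, "gc_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("stats", c("assembly_stats.tsv", "gc_windows.tsv"),
         list(N50 = st$N50, mean_gc = mean(gc$gc)))
    list(assembly = st, gc = gc)
  })

  res$anchor <- stage("anchor", {
    p <- cfg$anchor
    frag <- res$simulate$frag
    mk <- simulate_markers(frag$contigs, frag$layout, p$n_markers,
                           p$marker_length, seed = cfg$seed + 3L)
    lg_map <- setNames(mk$truth$linkage_group, mk$truth$marker_id)
    hits <- align_markers(mk$markers, frag$contigs, lg_map)
    kept <- filter_marker_hits(hits, p$min_identity, p$min_coverage, p$top)
    asn <- assign_linkage_groups(kept)
    summ <- anchoring_summary(asn, kept, length(mk$markers), frag$contigs)
    write.table(asn[, c("target_id", "assigned_lg", "n_markers", "status")],
                file.path(outdir, "lg_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("anchor", "lg_assignments.tsv",
         list(marker_fraction = unname(summ["marker_fraction"]),
              length_fraction = unname(summ["length_fraction"])))
    list(markers = mk, hits = kept, assignments = asn, summary = summ)
  })

  res$synteny <- stage("synteny", {
    p <- cfg$synteny
    frag <- res$simulate$frag
    ref <- mutate_reference(res$simulate$genome, divergence = p$divergence,
                            seed = cfg$seed + 4L)
    aln <- simulate_alignments(frag$layout, ref$block_map, chunk_size = p$chunk,
                               identity = 100 * (1 - p$divergence))
    aln11 <- filter_one_to_one(aln)
    blocks <- build_blocks(aln11, min_block = p$min_block, max_gap = p$max_gap)
    bs <- block_stats(blocks, frag$contigs, rearrangement_min = p$rearr_min)
    oc <- order_contigs(blocks)
    links <- links_from_ordering(oc$ordering)
    rec <- reconcile_links(links, lg_assignments = res$anchor$assignments)
    write_alignments(aln11, file.path(outdir, "alignments_1to1.tsv"))
    write.table(blocks, file.path(outdir, "synteny_blocks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("synteny", c("alignments_1to1.tsv", "synteny_blocks.tsv"),
         list(n_blocks = bs$n_blocks, coverage = bs$coverage,
              block_n50 = bs$block_n50, links_rejected = nrow(rec$rejected)))
    list(reference = ref, blocks = blocks, stats = bs, ordering = oc,
         links = rec)
  })

  res$scaffold <- stage("scaffold", {
    p <- cfg$scaffold
    sc <- emit_scaffolds(res$synteny$ordering$ordering,
                         res$simulate$frag$contigs, gap_length = p$gap_n)
    write_fasta(sc$scaffolds, file.path(outdir, "scaffolds.fa"))
    write_agp(sc$agp, file.path(outdir, "scaffolds.agp"))
    note("scaffold", c("scaffolds.fa", "scaffolds.agp"),
         list(n_scaffolds = length(sc$scaffolds)))
    sc
  })

  res$gapclose <- stage("gapclose", {
    p <- cfg$gapclose
    layout <- res$synteny$ordering$ordering
    ov <- find_end_overlaps(layout, res$simulate$frag$contigs,
                            min_identity = p$min_identity,
                            min_len = p$min_len, end_window = p$end_window)
    gc <- close_gaps(layout, res$simulate$frag$contigs, ov)
    write_fasta(gc$contigs, file.path(outdir, "contigs_closed.fa"))
    write.table(ov, file.path(outdir, "end_overlaps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("gapclose", c("contigs_closed.fa", "end_overlaps.tsv"),
         gc$report)
    gc
  })

  res$repeatscan <- stage("repeatscan", {
    p <- cfg$repeatscan
    genome <- res$simulate$genome
    occ <- scan_monomer(genome$haplotype_a[["chr1"]], p$monomer,
                        both_strands = TRUE)
    arrays <- tandem_arrays(occ[occ$strand == "+", ], nchar(p$monomer),
                            max_spacer = p$max_spacer,
                            min_copies = p$min_copies)
    prof <- density_profile(occ, nchar(genome$haplotype_a[["chr1"]]),
                            p$window)
    write.table(arrays, file.path(outdir, "tandem_arrays.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(prof, file.path(outdir, "monomer_density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("repeatscan", c("tandem_arrays.tsv", "monomer_density.tsv"),
         list(n_occurrences = nrow(occ), n_arrays = nrow(arrays),
              max_copy_number = if (nrow(arrays)) max(arrays$copy_number) else 0L))
    list(occurrences = occ, arrays = arrays, profile = prof)
  })

  res$chain <- stage("chain", {
    p <- cfg$chain
    ## B-chromosome analogue: read placements clustered on a few donor
    ## chromosomes of the assembly
    reads <- res$simulate$reads
    donors <- head(unique(reads$chrom), p$n_donor_chroms)
    sel <- reads[reads$chrom %in% donors, ][seq_len(p$n_reads), ]
    placements <- data.frame(target_id = sel$chrom, start = sel$start,
                             end = sel$start + nchar(sel$sequence))
    ps <- chain_placements(placements, max_gap = p$max_gap)
    lg <- data.frame(target_id = donors[1], assigned_lg = "LG1",
                     stringsAsFactors = FALSE)
    comp <- homology_composition(ps, lg)
    write.table(ps, file.path(outdir, "pseudo_scaffolds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(comp, file.path(outdir, "homology_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("chain", c("pseudo_scaffolds.tsv", "homology_composition.tsv"),
         list(n_pseudo_scaffolds = nrow(ps)))
    list(pseudo_scaffolds = ps, composition = comp)
  })

  invisible(res)
}
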