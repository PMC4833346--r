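Package: scafkit
Title: K-mer Spectrum Genome Profiling, Assembly QC and Reference-Guided
    Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a chromosome-level
    fish genome assembly project: canonical k-mer spectrum counting and
    two-component negative-binomial mixture modelling of genome size and
    heterozygosity; assembly QC statistics (Nx/Lx, GC window profiles,
    clone-end pair concordance); linkage-map marker anchoring with
    identity/coverage filters and majority-vote linkage-group assignment;
    collinear synteny-block construction from 1:1-filtered whole-genome
    alignment tables with contig ordering, link reconciliation and AGP/FASTA
    scaffold emission; contig end-overlap detection and trim-and-concatenate
    gap closure; tandem monomer (telomere-style) array scanning; and
    pseudo-scaffold chaining of read placements across sub-threshold gaps.
    A seeded synthetic-data generator produces diploid genomes, reads,
    fragmented assemblies, markers and rearranged reference genomes with
    known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    minpack.lm,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
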