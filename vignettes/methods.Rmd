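---
title: "Models and methods behind scafkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scafkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafkit)
```

scafkit re-implements, as tested R functions, the custom computational
steps of a chromosome-level genome assembly project for a diploid fish
genome: spectrum-based genome profiling, assembly QC, marker anchoring,
reference-guided scaffolding, overlap-based gap closure, tandem-repeat
scanning, and pseudo-scaffold chaining. This vignette explains the models,
the parameters that matter, the numerical choices, and what the synthetic
data used by the test suite does and does not establish.

## The two-component negative-binomial spectrum model

The k-mer spectrum of whole-genome reads from a diploid individual is
bimodal: homozygous k-mers appear at the full diploid coverage, while
heterozygous k-mers — carried by one haplotype only — appear at half that
coverage. `fit_mixture()` models the spectrum K(x) as

$$K(x) = s_1\,\mathrm{NB}(x;\,\mu,\,\mathrm{size}_1) +
         s_2\,\mathrm{NB}(x;\,2\mu,\,\mathrm{size}_2),$$

with negative binomial components parameterized by mean and dispersion
($\mathrm{Var} = \mu + \mu^2/\mathrm{size}$), the second component's mean
constrained to exactly twice the first. The scale factors $s_1, s_2 \ge 0$
absorb genome size and heterozygosity. Fitting is ordinary nonlinear least
squares (bounded Levenberg–Marquardt via minpack.lm), mirroring the common
practice of fitting spectra with `nls`.

Assumptions worth keeping in mind:

* **SNP-centric heterozygosity.** Each heterozygous base contributes $k$
  heterozygous k-mers per haplotype; indels break this accounting and are
  deliberately outside the model (and outside the simulator).
* **No repeat component.** The fit window is capped at $4\mu_0$ (initial
  peak estimate) so repetitive k-mers do not distort the two components;
  repeat mass is visible to `genome_size()` only through the total-mass
  estimator.
* **Clustered SNPs undercount.** SNPs closer than $k$ bases share k-mers,
  so the derived rate slightly undercounts — the reason a fitted rate is
  best read as a narrow range rather than a point.

Derived quantities, with `H` and `D` the summed fitted component
densities over the fitted multiplicity range:

* heterozygosity rate $= \dfrac{H/2k}{H/2 + D}$;
* non-repetitive genome size $= H/2 + D$ bases;
* total genome size $= \sum_{x \ge \mathrm{cutoff}} x\,K(x) \,/\, 2\mu$.

### Numerical choices in the fit

* **Error cutoff.** Sequencing errors produce a large mass of
  low-multiplicity k-mers. The default cutoff is the first local minimum
  of the window-3 smoothed spectrum (the visible trough), floored at 3 and
  user-overridable (`fit_cutoff`).
* **Initialization and restarts.** When the two components are broad they
  merge into a single hump whose mode is neither $\mu$ nor $2\mu$, so a
  single starting point is unreliable. The fitter tries the smoothed-peak
  guess, the raw mode, and half the mode as $\mu$ starts (dispersion 5,
  scales from peak heights), with a deterministic jitter schedule as
  fallback on failure, and keeps the fit with the smallest residual sum of
  squares. Convergence is `ftol = 1e-10`, `ptol = 1e-8`, at most 500
  iterations per start.
* **Degenerate (single-peak) spectra.** A fully homozygous sample has no
  heterozygous peak, and the unconstrained mixture will happily split one
  peak across both components. Two safeguards apply: (i) a parsimony
  fallback fits a homozygous-only model ($s_1 = 0$) and prefers it when
  its residual is within 5% of the two-component optimum; (ii) if the
  two-component fit itself drives $s_2 \to 0$, the lone component is
  relabelled as the homozygous one at half its fitted mean — in a diploid
  spectrum heterozygous mass cannot exist without homozygous mass, so a
  lone peak is the homozygous peak. Both paths set `degenerate = TRUE`.
* **k must be odd** so that no k-mer equals its own reverse complement
  under canonical counting (k = 21 is the conventional profiling choice;
  the counter accepts 1–31 so the toy examples in the documentation stay
  checkable by hand).

## Assembly statistics

`nx_stats()` is the standard descending-cumulative-sum definition.
`gc_windows()` tiles sequences with non-overlapping windows by default
(stride configurable down to sliding), computes GC over non-N bases, and
discards windows with *strictly more than* 25% N — the boundary window at
exactly 25% is retained. `classify_end_pairs()` calls a clone-end pair
proper when both ends hit one target, convergently oriented, with the
separation measured between the **outermost** aligned coordinates (insert
size semantics) inside [50 kb, 250 kb]; the four categories are mutually
exclusive and exhaustive.

## Marker anchoring

Hits are filtered per marker: top five by alignment score (ties at rank
five all kept, since the ranking key is not part of the rule), then the
best marker-alignment coverage (ties on different targets all kept), then
identity ≥ 90% and coverage ≥ 80%. Coverage is that of the single best
HSP, not summed HSPs. Linkage groups are then assigned to targets by
plurality over distinct retained markers — a deterministic, reportable
replacement for manual inspection: ties leave the target `conflicted` and
unassigned rather than silently resolved.

## Synteny blocks and scaffolding

`filter_one_to_one()` enforces single coverage on both genomes greedily by
descending score. Overlaps at alignment ends are **trimmed** (consistently
in both coordinate systems, respecting strand) rather than dropping the
whole alignment — neighbouring contigs genuinely share a few hundred bases
where they overlap, and dropping whole records would delete short contigs
from the analysis; records fully covered, split internally, or left under
`min_keep` (100 bp) are dropped.

`build_blocks()` chains same-(query, target, orientation) alignments that
are monotone in both genomes with gaps ≤ `max_gap` into collinear blocks,
in two passes: blocks spanning < 6000 bp after pass 1 are treated as
spurious, their members removed, and the remainder re-chained, letting
runs interrupted by a short discordant block merge. The boundary is
strict: a block of exactly 6000 bp is retained. `max_gap` defaults to
50 kb — large enough to bridge local alignment dropouts at a few percent
divergence, small enough not to chain across genuine rearrangements; it is
configurable because the right value scales with divergence.

`block_stats()` counts intrachromosomal rearrangements per target
chromosome as maximal runs of target-adjacent blocks in the minority
(span-weighted) orientation, merged across target gaps ≤ `max_join`, and
counted when the run's target span exceeds 200 kb. Counting *events*
rather than blocks makes the census independent of how finely the query
side is fragmented into contigs.

`order_contigs()` places each contig on the chromosome holding its
largest summed block span, sorted by span-weighted midpoint, oriented by
span-weighted majority. Placement requires **clear dominance**: when the
runner-up chromosome holds more than half the dominant span (e.g. a 60/40
split), the contig is reported unplaced instead of guessed — a deliberate
conservative reading, since mis-placement is costlier downstream than a
reported gap. `reconcile_links()` rejects adjacency links contradicted by
an independent partial order (non-adjacent in a map-derived contig
sequence) or joining different assigned linkage groups, keeps accepted
links as simple paths, and treats a cycle as an error. `emit_scaffolds()`
joins oriented contigs with 100 N (configurable) and emits AGP v2.1
(1-based inclusive, per the standard; all internal coordinates are
0-based half-open).

## Gap closure

`find_end_overlaps()` orientation-normalizes neighbouring contigs (so all
comparisons are +/+; reverse-strand end matches are never used) and looks
for end-of-left to start-of-right overlaps within 10 kb of the termini:
candidate lengths come from exact 20-mer seeds taken at several offsets
from the left contig's end, each verified by full ungapped comparison at
≥ 95% identity; the longest qualifying overlap wins. The minimum length
defaults to 100 bp — the identity threshold is the documented rule, the
length floor merely suppresses spurious seed hits, and both are
configurable. `close_gaps()` trims the overlap from the left contig and
concatenates the right one (the right contig's copy of the overlap is
kept verbatim on mismatch), propagating merges transitively along each
scaffold; an overlap consuming an entire contig is an error naming the
pair.

## Repeats and pseudo-scaffolds

`scan_monomer()` reports **exact** occurrences only (both strands on
request); a mismatch-tolerant mode is out of scope since array statistics
are defined over exact monomer runs. Overlapping occurrences of
self-overlapping monomers are all reported and then consumed
leftmost-greedily during `tandem_arrays()` chaining: occurrences spaced
exactly one monomer apart extend perfect arrays, spacings up to
`max_spacer` form interrupted trains, and an occurrence starting inside
the current array extends nothing but belongs to it — so with
`min_copies = 1` every occurrence belongs to exactly one reported array.

`chain_placements()` merges read placements per target when the gap is
*strictly* less than `max_gap` (default 10 kb, matching the stated rule);
the merge is sort-based and therefore independent of input order.
`homology_composition()` sums pseudo-scaffold spans per linkage group with
an explicit `unassigned` bucket; spans, not summed read bases, are the
reported quantity.

## The synthetic-data generator

The generator emulates the study conditions: a diploid genome with ~0.4%
SNP heterozygosity, reads at tens-fold coverage with substitution errors,
an assembly fragmented into contigs with planted 200–500 bp end-overlaps,
markers drawn from contigs on known linkage groups (= source
chromosomes), a related reference at a few percent divergence with planted
≥ 10 kb inversions and reciprocal translocations, and read placements
clustered on a few donor chromosomes. Every operation takes a single
integer seed and is reproducible; all ground truth (SNP positions, contig
layout, planted overlaps, block maps, marker sources) is recorded.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* **Substitutions only** — no indels in haplotype divergence, reads, or
  reference divergence; real data's indel errors broaden and shift
  spectrum peaks and break exact overlap detection at homopolymers.
* **Uniform coverage** — no GC bias, no chimeric reads, no
  quality-score structure (FASTQ qualities are written as constant Q40).
* **Contigs at least 10 kb** by default (`min_contig`): long-read
  assembler contigs below the ~10 kb scale are rare, and
  reference-guided placement of such fragments is unreliable by
  construction; cut positions are otherwise uniform.
* **Truth-derived alignments.** `simulate_alignments()` projects contigs
  through the true block map instead of running an aligner, so the
  synteny tests certify the chaining/ordering/reconciliation logic on
  clean 1:1 tables, not robustness to aligner artefacts (repeat-induced
  multi-mappings, alignment breakpoint wobble).
* The B-chromosome analogue tests interval chaining and composition
  accounting, not read mapping.

## Problem sizes used by the test suite

The suite exercises parameter recovery on twenty seeded 1 Mb diploid
simulations at 36× with 0.5% error (median relative error ≤ 5% for the
fitted peak and ≤ 25% for heterozygosity), scaffolding recovery on a
10-chromosome, 10 Mb genome at 20 contigs per chromosome against a 2%
diverged reference (≥ 95% of true adjacencies, and an exact census of
three planted 250 kb inversions), and byte-exact gap-closure
reconstruction on two 100 kb chromosomes — sizes chosen so each property
is measured at a scale where its failure modes can actually appear while
the whole suite stays fast. Brute-force oracles (cumulative-sum Nx, naive
sliding-window monomer scan, positional coverage tabulation) back the
statistics on hundreds of random small instances.

## Known limitations

* The mixture model has no repeat component; genomes with high repeat
  content inflate the total-size estimator and are only partially
  shielded by the $4\mu_0$ window.
* Spectra where the two peaks merge completely (very high dispersion or
  very low coverage) are resolved by residual comparison among candidate
  starts, which can prefer the degenerate reading when coverage is a few
  fold; profiling below ~15× is not recommended.
* Two-reference scaffolding is supported by running `order_contigs()` per
  reference and intersecting links; the default tested path is
  single-reference.
* Manual curation steps of real assembly projects (splitting/joining
  linkage groups, resolving conflicted contigs by inspection) are
  represented only as reported conflicts.
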