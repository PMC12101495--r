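---
title: "Genome-resolved fecal source tracking: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-resolved fecal source tracking: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstrack)
```

## The problem

Fecal contamination of surface waters has to be traced back to its
sources — municipal wastewater, septage, livestock, pets, wildlife — before
it can be managed. Marker-gene methods answer "is source X present?" one
assay at a time; `fstrack` instead treats the whole shotgun metagenome as
the assay. Reads are mapped against a database of genomes with known source
associations, mapped signal is converted to an estimate of the fraction of
*cells* in the sample that belong to each source, and simple decision rules
turn those fractions into presence calls and source proportions.

## The model

### Cell fractions via genome equivalents

For source category $j$ with member genomes $i = 1..n$ (source-specific and
cross-reactive alike), the estimated cell fraction is

$$\widehat{f}_j \;=\; \sum_{i \in j,\ \mathrm{detected}} \frac{X_i}{\mathrm{GEQ}}$$

where $X_i$ is genome $i$'s mean per-base coverage depth after alignment
filtering and GEQ is the metagenome's total genome equivalents — total
sequenced bases divided by the community's average genome size (AGS). Depth
over GEQ is, in expectation, the number of genome copies of $i$ per genome
copy in the whole community, i.e. a relative cell abundance, provided each
species contributes one genome per cell.

Two GEQ backends exist. The default test path estimates GEQ from universal
single-copy markers: if marker $m$ (length $L_m$) receives $B_m$ aligned
bases, then $B_m / L_m$ estimates the total genome-copy count, and the
estimate is the median over markers with hits (robust to an individual
marker's sampling noise). Alternatively a known AGS (e.g. from an external
AGS estimator) can be supplied and GEQ $= \mathrm{bp}_{\mathrm{total}} /
\mathrm{AGS}$.

### Presence and apportionment

A fecal source is called **present** only if both of:

1. at least one *source-specific* genome of the category is detected, and
2. the category cell fraction strictly exceeds the limit of detection
   (LOD; default 0.01% relative abundance).

Signal carried entirely by cross-reactive genomes — genomes with a ≥ 95%-ANI
relative in another category — is disregarded: it establishes nothing about
*which* of the sharing categories is present. For present sources,

$$\mathrm{portion}_j = \frac{\widehat{f}_j}{\sum_{i\ \mathrm{present}} \widehat{f}_i},$$

using the *full* (specific + cross-reactive) fractions. Because the same
GEQ divides numerator and denominator, portions are exactly invariant to
uniform misestimation of GEQ — cell fractions can be biased while portions
stay accurate, and the test suite pins this invariance.

### Cross-reactivity, screening, aggregation

Cross-reactivity flagging is purely database-level: genome pairs in
different categories with ANI ≥ 95% (both directions considered; the larger
value decides) are flagged symmetrically. Same-category pairs are never
flagged — within a category, shared species simply share signal.

An optional **environmental screen** category holds autochthonous genomes
of the receiving water. Its fraction is computed and reported, but it is
excluded from attribution and apportionment; its role is to absorb
background reads that would otherwise land on cross-reactive fecal genomes.
The test suite demonstrates the direction of this effect: on a
background-heavy simulation with an engineered environment/pig shared
species, removing the screen creates pig false positives that the screened
database does not make.

An **aggregation rule** (e.g. human → wastewater) moves a category's signal
into a target category before reporting. Aggregated signal is counted in
the target's *cross-reactive* component: it contributes abundance but can
never satisfy the target's specific-genome condition. This implements the
reporting convention of folding human-specific signal into wastewater
without letting it alone trigger a wastewater call. (We deliberately do not
fabricate partner entries in the flag table for aggregated genomes; the
flag invariant — flagged iff a partner list is non-empty — stays intact.)

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_identity` | 93 | % | minimum read-to-genome alignment identity, $100(\mathrm{aligned} - \mathrm{NM})/\mathrm{aligned}$ |
| `min_overlap` | 70 | % | minimum aligned fraction of the read, $\mathrm{aligned}/\mathrm{read\ len}$ |
| `masking_percent` | 0 | % | extreme-coverage positions excluded before averaging depth |
| `lod_percent` | 0.01 | % rel. abundance | presence threshold on the category cell fraction (strict >) |
| `min_reads`, `min_breadth` | 1, 0 | — | per-genome detection rule |
| `ani_threshold` | 95 | % | cross-reactivity flagging boundary (inclusive ≥) |

The identity threshold is the workhorse: it separates reads of the database
species (≈ 0–2% divergence at read length) from reads of congeneric
relatives (≥ 5–10% divergence). Overlap mainly removes spurious soft-clipped
placements. Both filter thresholds are *inclusive* (≥); the LOD is *strict*
(>): a fraction exactly at the LOD is not "exceeding" it. These boundary
conventions are pinned by tests.

Identity is NM over aligned query bases (the accounting used by common
coverage tools), not gap-compressed identity. Aligned length counts CIGAR
M/=/X operations; read length includes soft- and hard-clipped bases.

"Masking" is implemented as symmetric trimmed-mean coverage: with masking
$m$%, the $m/2$% highest- and lowest-coverage positions of each genome are
excluded before averaging. The tuned default of 0% makes the default path a
plain mean; the interpretation therefore only affects the tuning grid. The
trimmed mean is only guaranteed monotone in $m$ for right-skewed coverage,
which is how the property is tested.

The per-genome detection rule (≥ 1 filtered read by default, optional
breadth floor) is stated explicitly because "detected" is otherwise
ambiguous at very low coverage; it is recorded in every serialized run
configuration.

## Parameter tuning

`run_parameter_grid()` scores every combination of identity × overlap ×
masking × LOD against a ground-truth table. The default grid is
{85, 87, 89, 91, 93, 95, 97, 99} × {30, 50, 70, 90} × {0, 25, 50, 75} ×
{0.1, 0.01, 0.001, 10⁻⁴, 10⁻⁵} — 640 combinations bracketing the default
optimum. The grid values other than the optimum and the 30–90% overlap range
are this package's own bracketing choices and are config-overridable.

The objective is **negative predictive value** (TN/(TN+FN)) — in source
tracking a false "all clear" is the costly error — with ties broken by
higher sensitivity, then higher specificity, then by the parameter values
themselves so the ranking is total and deterministic. Ratios with zero
denominators are reported as missing, never as zero. Filtering is performed
once per (identity, overlap) pair and depth once per masking value, then
reused across LODs; a test verifies this equals the naive
recompute-everything loop.

GEQ is held fixed per sample across the grid: it is a property of the whole
metagenome, not of mapping thresholds (the marker-based estimate would
otherwise drift with the filter being tuned, conflating normalization with
filtering).

The grid also reports an OLS calibration (true ~ predicted cell fraction).
It is diagnostic only and never applied automatically: genome databases
that capture only part of a source's diversity systematically underestimate
cell fractions, and the slope quantifies that bias without silently
"correcting" it.

## The synthetic benchmark generator

`generate_genomes()` / `true_cell_fractions()` / `simulate_reads()` emulate
ground-truth mixture experiments: a background water community spiked with
fecal communities at known cell densities $\rho_i$ and volumes $V_i$, so
the true cell fraction of source $i$ is exactly
$\rho_i V_i / (\sum_j \rho_j V_j + \rho_{bg} V_{bg})$.

Design choices, and what they mean for interpreting green tests:

- **Substitution-only errors, no indels.** Truth-SAM CIGARs are all-M and
  each read's identity is analytically known, which makes threshold
  behaviour exactly testable. Real data contain indels and quality-skewed
  errors; the filter handles arbitrary CIGARs, but the simulator does not
  exercise them (hand-built SAM fixtures do).
- **Equal-length genomes, equal copies within a category.** Read fractions
  then equal cell fractions exactly, so recovery tests have exact targets.
  A geometric `skew` option emulates rank-abundance effects but is off by
  default. Real communities are neither equal-copy nor equal-length.
- **Embedded universal markers.** Each marker occurs exactly once per
  genome, so total marker coverage equals total genome copies by
  construction and the marker-GEQ backend has a known truth. Because the
  markers are *identical* across genomes, a real aligner scatters marker
  reads across categories (ties broken arbitrarily) and can create spurious
  low-level detections; benchmark fixtures that go through `bwa` therefore
  use `n_markers = 0` with a supplied AGS, while truth-SAM fixtures (reads
  assigned to their origin genome) use the marker backend. Real universal
  marker genes are conserved but not identical, putting real data between
  these two regimes.
- **Truth SAM vs real alignment.** The simulator emits the origin
  coordinates as a SAM, which removes the aligner from most tests. Effects
  that *require* reads to compete across genomes — cross-reactive signal
  spilling between near-identical genomes, screen-ablation false
  positives — cannot be expressed in an origin-truth SAM, so those tests
  align the simulated FASTQ with `bwa mem` through the package's wrapper.
- **Determinism.** All randomness flows from one explicit seed; equal seeds
  give byte-identical FASTQ/SAM, and the seed is recorded in every output
  header.

Passing tests on these simulations demonstrate the pipeline's arithmetic,
decision logic, and directional behaviour under controlled conditions; they
do not demonstrate performance on real mesocosm or field data, where
database completeness (the dominant error source), chimeric reads, strain
variation, and non-uniform coverage all intrude.

## Numerical and degenerate-input choices

- The ANI estimator uses non-overlapping 1 kb fragments, 15-mer seeding,
  ungapped extension, best strand per fragment, and discards fragments
  below 80% identity; seeding ties resolve to the leftmost reference
  position. It targets coarse discrimination around the 95% species
  boundary, not fastANI parity; with substitution-only divergence it tracks
  the exact Hamming identity to within ±0.5 points in tests. Queries
  shorter than one fragment fall back to a single truncated fragment with a
  warning; sequences sharing no seed k-mer get an undefined ANI (reported
  as missing, not 0).
- Cross-category ANI pairs missing from the table are treated as below
  threshold; flagging uses max(ANI(A,B), ANI(B,A)) since fragment-based ANI
  is asymmetric.
- Coverage is accumulated with a per-genome difference array (exact,
  linear time), genome coordinates concatenate contigs, and alignments
  overhanging a contig end are clipped with a counted warning.
- Mapped records without an NM tag are skipped with a counted warning; an
  alignment referencing a contig absent from the database is a hard error
  (it means reads were mapped against a different reference).
- A sample with no present source produces an explicit all-absent report,
  not an empty file; apportionment of nothing is an empty map.
- Undefined rates (zero denominators) and undefined correlations (constant
  vectors) are NA throughout.

## Problem sizes used in the test and acceptance runs

The bundled benchmarks use toy genomes of 5–20 kb, 2–4 genomes per
category, and 2 × 10³ to 2 × 10⁵ reads of 150 bp; the end-to-end mixed
design (10% wastewater + 5% × five animal sources over a 65% lake-water
background) uses 2 × 10⁵ reads against a 22-genome database. These sizes
give per-genome depths of 10–100× — comfortably above detection — while the
LOD, grid, and ablation behaviours are exercised at realistic relative
scales. They are the package's chosen benchmark conditions, small enough to
regenerate everywhere, and deliberately not a claim about sequencing-effort
requirements on real samples.

## Known limitations

- Attribution quality is bounded by database coverage of each source's
  diversity; a source whose genomes are missing is reported absent (the
  ablation tests show this failure mode directly), and partially covered
  sources underestimate cell fractions.
- Multi-mapping is resolved by the aligner's primary flag; the package does
  not re-assign reads, so near-identical genomes trade signal
  arbitrarily (cross-reactivity flags are the defence, not read-level
  reassignment).
- The bundled ANI estimator is coarse by design; for publication-grade
  databases an external ANI table is the better input.
- Paired-end mates are treated as independent reads.
- Cell-fraction estimates inherit any bias in GEQ estimation; portions are
  robust to uniform GEQ bias but not to source-specific mapping bias.
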