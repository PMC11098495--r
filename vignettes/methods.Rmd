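---
title: "Models and methods for binned contact-map analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for binned contact-map analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models, parameter conventions, and
the genuinely open design decisions behind each module, in the way a
maintainer or reviewer would want them stated. It asserts no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## Data model

A contact store is one resolution of a cooler-schema HDF5 file: a
chromosome table, a bin table tiling each chromosome in fixed steps
(0-based, half-open coordinates), and a strictly upper-triangular,
sorted, duplicate-free pixel table of `(bin1_id, bin2_id, count)`.
Balancing weights are multiplicative — the balanced value of a pixel is
`count * w_i * w_j` — and a missing weight marks a filtered-out ("bad")
bin whose every balanced value is missing. This matches the cooler
convention, so files balanced by other software are consumed as-is.

Weight scaling is not standardized in the wild (genome-wide versus
per-chromosome balancing differ between pipelines). The bundled
`iterative_correction()` is fixture-grade plumbing, not a user-facing
balancing feature: it drops bins whose raw marginal falls below the 2nd
percentile of nonzero marginals, runs symmetric Sinkhorn-style updates to
tolerance `1e-6`, and rescales so the mean nonzero balanced pixel equals 1.
That last convention is this package's own choice, made so that balanced
values of synthetic fixtures are O(1); analyses never depend on it because
every downstream statistic is scale-free (observed/expected, log-ratios,
eigenvector signs).

A genomic *view* — ordered, named, non-overlapping regions, e.g.
chromosome arms split at centromeres — defines the coordinate system of
every per-region analysis. A bin belongs to the region containing its
start coordinate.

## Expected / P(s)

`expected_cis()` aggregates, per region and per separation `d` (in bins;
bp conversion happens only at output), the count sum and balanced sum over
one chunked pass of the pixel table. `n_valid(d)` counts pairs `(i, i+d)`
with both bins valid, computed combinatorially from the validity vector,
so the average is exact under arbitrary masking. `count_sum` deliberately
includes pixels touching bad bins, so that summing over all records
conserves the store's total cis count (a conservation test pins this);
`balanced_sum` covers valid pairs only. Pairs of distinct same-chromosome
regions (inter-arm) are reported as rectangle records without a distance
index.

Smoothing replaces the per-distance ratio with a Gaussian-kernel weighted
mean in `log10(d)`: kernel width `sigma_log10 = 0.1` decades, truncated at
3 sigma, with kernel weights multiplied by `n_valid`. Weighting by
`n_valid` (rather than by raw pixel count) keeps sparsely sampled long-range
distances from being dominated by a few surviving pixels; this choice is
pinned by an explicit kernel oracle in the tests. Distances below
`min_dist = 2` bins pass through unsmoothed and are excluded from the
kernel support, because the first diagonals are dominated by ligation
artifacts and would otherwise leak into neighbouring distances. With
`aggregate = TRUE`, sums and `n_valid` are pooled across regions before
smoothing, giving one genome-wide curve. The P(s) derivative is a central
finite difference of `log10 P` against `log10 s` on the smoothed curve,
one-sided at the ends.

## Compartments

For cis profiles, each region's balanced matrix is divided
diagonal-by-diagonal by its within-region mean (observed/expected),
symmetric-clipped at the 0.1 and 99.9 percentiles to tame sparse-diagonal
outliers (the percentile pair is this package's choice and is exposed),
centered by subtracting 1 — not row-mean centering, so the decomposition
matches "divide by expected, then decompose" — symmetrized as
`(M + t(M))/2` to remove numerical asymmetry, stripped of bad rows and
columns, and eigendecomposed. Eigenvalues are ordered by signed value
descending, since compartmentalization is a positive-association pattern.
Vectors are unit-norm over valid bins with missing values reinserted at
bad bins. A region with fewer than `n_eigs + 1` valid bins yields an
all-missing result with a warning rather than an error, so one degenerate
arm does not abort a genome-wide run.

For trans profiles, the genome-wide matrix has each cis block replaced by
values drawn uniformly (seeded) from the valid trans pixels involving that
chromosome, is scaled by the global trans mean, and is then centered and
decomposed the same way. Using a global rather than per-chromosome-pair
trans mean is the simpler of the two defensible conventions; the per-pair
variant would only rescale blocks and is noted as an extension.

Because eigenvectors are defined up to sign and the compartment signal is
not always the leading vector, `phase_eigs()` orients each vector by the
sign of its Pearson (optionally Spearman) correlation with a phasing track
(typically GC content) over jointly valid bins, and with
`sort = "correlation"` reorders vectors by descending absolute correlation.

## Saddles

`digitize_track()` cuts a track into `n_classes = 5` classes at quantiles
linearly spaced between `lo_q = 0.025` and `hi_q = 0.975` of the valid
values; values outside that range go to outlier classes `0` and
`n_classes + 1`, which are excluded from the saddle by default. Trimming
2.5% per tail is this package's default for robustness to extreme bins and
can be disabled (`lo_q = 0, hi_q = 1`).

`saddle_aggregate()` averages observed/expected over every usable bin pair
per class pair. The numerator comes from a chunked scan of stored pixels;
the denominator counts *all* valid in-range bin pairs combinatorially, so
bin pairs with zero observed counts correctly contribute zeros to the
average — on sparse maps this matters enormously (ignoring them biases
every entry upward). Cis aggregation uses the distance-indexed expected of
the pixel's own region and skips `d < min_dist = 2` consistent with the
expected module; trans uses region-pair averages. Accumulation in both
orders with same-class pairs counted once makes `S` exactly symmetric.
`saddle_strength()` is the standard corner summary
`(mean TL + mean BR) / (2 * mean of pooled anti-diagonal corners)`.

## Insulation and boundaries

The diamond at bin `i` with window `w` bins is
`{(a, b): i−w ≤ a ≤ i < b ≤ i+w}`: it excludes self-pairs (`a = b`) and
includes distance-1 pixels, a definition pinned against a dense oracle.
The raw score is the *mean* balanced value over valid pairs in the
diamond. The field is split between mean and sum conventions; the mean is
used here because it is invariant to how much of the diamond survives
masking, and the normalization `log2(raw_i / mean(raw))` over the region
makes profiles comparable across regions and depths. Scores are missing
within `w` of region edges and wherever `n_valid_pairs / w² <
min_valid_frac` (default 0.66). The profile is accumulated from sparse
pixel chunks by range-addition (difference arrays), and equals the dense
computation to float tolerance at any chunk size.

Minima are bins strictly below both flanking finite scores; for plateaus
the leftmost bin is reported and flagged. Prominence is the smaller, over
the two directions, of the highest score met walking outward until
reaching a deeper point or the region end, minus the minimum's score — so
a shallow minimum next to a deep one is capped by the saddle between them.
Prominence is invariant to constant shifts of the profile. Strong
boundaries are selected per window size by Otsu (exhaustive
between-class-variance maximization over the observed prominences) or Li
(minimum cross-entropy fixed point) thresholds, implemented directly on
the 1-D sample rather than on a binned histogram because prominence sets
are small; a fixed numeric threshold is also accepted.

A planted boundary in the synthetic maps is an *edge* between bins
`b−1` and `b`. Recovery in the tests therefore measures the distance from
a detected minimum to the nearer of the two junction-flanking bins: at the
tested depth the valley bottom is flat over 2–3 bins and its argmin
wobbles by one bin around the edge, which is a property of the statistic,
not of the implementation.

## Dots

Scoring follows the HiCCUPS scheme. The four stock kernels at outer
half-width `w = 5`, inner `p = 2` (10 kb scale; scaled by resolution in
practice) are background masks around a candidate pixel: a donut excluding
the center row/column, vertical and horizontal bands, and the lower-left
quadrant toward the diagonal; exact masks are pinned as printed matrices
in the tests, and user masks are accepted. For pixel `(i, j)` and kernel
`k`, `f_k = Σ obs / Σ exp` over valid kernel cells and
`λ_k = f_k · E(|i−j|)/(w_i w_j)` is an expected *raw* count. Maps are
scored in overlapping square tiles (overlap = kernel half-width) so each
pixel is scored once with full context; tile-size independence is asserted
exactly. A pixel is dropped when any kernel has under half of its cells
valid — the background factor is a ratio estimator and remains stable from
half of even the smallest stock kernel (24 cells), while a stricter floor
was observed to discard scoreable pixels near clustered masked bins. All
pixels in the scored band enter the FDR stage, including zero-count ones:
they are real tests.

Significance uses lambda-chunked BH: chunks at geometric edges
`(2^{1/3})^m`, p-values from the upper-tail Poisson probability evaluated
at the chunk's *upper* edge (conservative, the HiCCUPS convention), BH
within each chunk at `fdr_q = 0.1`, and a pixel is retained only if
significant under every kernel (the strictest of the defensible gating
rules; relaxable). Retained pixels are single-linkage clustered within
`radius_bp = 39000` (adjacent/touching pixels at 10 kb), the most
significant pixel represents each cluster, and centroids must reach donut
and lowerleft enrichment `≥ 1.75`.

Detectability on the synthetic maps is governed by counting statistics:
at depth 10⁶ on the default fixture, a 3–5× enrichment is resolvable
against BH only where the expected count is a few per pixel, i.e. at
separations up to roughly 300 kb. The dot fixtures therefore plant
anchors at 50–250 kb separations, which is also where mammalian loops
concentrate (median anchor separation ≈ 200 kb). Recall is evaluated over
dots whose anchor bins survive masking, since a dot destroyed by the
bad-bin mask is not recoverable by any method; precision counts all calls.

## Snipping and pileups

Anchors map to the bin containing their interval midpoint; anchor pairs
are oriented so the first anchor precedes the second (no strand flipping —
that is downstream territory). Windows are `(2f+1)` bins square,
missing-padded at region edges so every snippet has identical shape;
`oe` mode divides each cell by the expected at its separation within the
anchor's region. Snippets may be fetched by any number of workers with
bit-identical results, because each snippet is an independent read.
Pileups are element-wise means or medians ignoring missing values, with a
per-cell count of contributing snippets.

## Coverage, downsampling, adaptive smoothing

Coverage sums pixel counts into both incident bins, with diagonal
self-contact pixels counted once by default (an option doubles them to
match balancing marginals). Downsampling draws an independent binomial per
pixel at the requested fraction — indistinguishable from
without-replacement sampling at contact-map scales — and writes a valid
cooler-schema file; it is seeded and exactly reproducible.

Adaptive smoothing builds a pyramid of 2×-coarsened matrices (raw counts
summed, balanced values averaged over valid cells, odd edges padded with
missing) and assigns each output cell the balanced value of the finest
level whose covering aggregate reaches `cutoff_counts`; cells failing
everywhere take the coarsest value, or missing where even the coarsest
aggregate is empty. The pyramid-selection formulation was chosen over
kernel-growing alternatives because it is deterministic and directly
testable against a per-cell oracle. On maps without missing data the
redistributed mass matches the input within about a percent; where masked
bins exist, filled-in cells add mass by design (they borrow their
neighbourhood's average), which is why the conservation property is stated
for mask-free maps.

## The synthetic generator

`map_recipe()` encodes the generative model: intensity
`base · max(d,1)^alpha · (1 + A v_i v_j) · depletion^{-crossings} ·
dot factor` in cis and `trans_level · (1 + A v_i v_j)` in trans, Poisson
counts at total depth `N`, a uniformly random bad-bin mask, and weights
from the bundled balancer. Defaults are the study conditions of the test
suite: two 3 Mb chromosomes at 10 kb (600 bins — large enough for FDR
statistics, small enough for dense oracles), `alpha = −1`,
`trans_level = 0.05` relative to the distance-1 cis intensity,
compartment blocks of 25 bins, domain depletion 4, Gaussian dot spots of
half-width 1 bin, 5% bad bins, depth 10⁶.

The generator emulates the features the analyses target — power-law
decay, checkerboard compartments, sharp insulating domains, focal dots,
masking, and Poisson sampling noise. It deliberately does not emulate
fragment-level biases, distance-dependent noise correlations,
translocations, or copy-number structure; passing its tests therefore
demonstrates correct recovery of planted structure under sampling noise,
not robustness to every artifact of real libraries.

## Interfaces and reproducibility contracts

Every CLI subcommand maps to exactly one API call with identical defaults
and writes headered TSV with a leading comment recording the version and
full argument list. Randomized paths (generation, trans cis-filling,
downsampling) take explicit seeds. The structural contracts — chunk-size,
tile-size, and worker-count independence, CLI/API serialization equality,
cooler round-tripping, fixed-seed determinism — are asserted in the
acceptance tests, and the problem sizes used throughout (600-bin fixtures,
20 null maps for the false-positive rate, 50 downsampling seeds) were
chosen so dense oracles stay exact and the whole suite remains a
few-minute run.

## Known limitations

Balancing is fixture-grade; publication-grade matrix correction should
come from the upstream pipeline. Trans dot calling, strand-aware pileups,
distance-stratified pileups, 2-D TAD segmentation, and multi-eigenvector
compartment clustering are out of scope; the API keeps the last of these
possible by allowing any number of eigenvectors. Dense per-region
materialization inside the eigendecomposition, dot scoring, and smoothing
modules assumes regions of at most a few thousand bins per region at the
chosen resolution.
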