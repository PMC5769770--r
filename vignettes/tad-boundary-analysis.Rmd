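---
title: "Methods: TAD boundary analysis with tadbound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAD boundary analysis with tadbound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadbound)
```

# Scope and model

`tadbound` implements a comparative chromatin-architecture workflow for a
locus where two topologically associating domains (TADs) meet at a
boundary whose strength is probed by an allelic series of deletions: Hi-C
pair processing to balanced contact matrices, insulation-based domain
calling with a multi-window consensus, 4C-seq viewpoint quantification,
in silico mutant genomes with exact liftover, and a ground-truthed
synthetic locus generator that makes every stage testable without
sequencing data.

## Hi-C processing

Mapped read ends are assigned to restriction fragments after shifting the
5' position 3 bp toward the 3' end, so reads starting exactly on a cut
site land in their true fragment. Same-fragment pairs are classified by
strand geometry — inward-facing pairs are unligated dangling ends,
outward-facing pairs self-circles, same-strand pairs mapping errors — and
discarded together with single-side mappings and exact duplicates
(replicates are concatenated before deduplication, so cross-replicate PCR
duplicates collapse). Valid pairs are binned by the midpoint of their
fragment (`floor(midpoint / bin_size)`; a midpoint exactly on a bin edge
goes rightward).

Bins are masked when their marginal falls 10-fold below the uniform
expectation `2 * pairs / bins` (each pair touches two marginals) or when
fewer than half of their fragments carry at least two reads ("less than
half" strict). Balancing is plain symmetric iterative correction:
marginals are equalised until the maximal relative deviation drops below
`tol = 1e-5` (at most 200 sweeps), the total unmasked sum is preserved,
and the accumulated per-bin biases are reported normalised to unit
geometric mean. No eigenvector step is used: only cis windows of a few
megabases are in scope, where compartment decomposition is irrelevant.
Subtraction operates on two balanced matrices under the union of their
masks, recording masked cells as missing rather than zero.

Domain-intensity comparison between conditions uses a two-sided Wilcoxon
rank-sum test on the unmasked off-diagonal within-domain values. For
small samples the p-value is computed by exhaustive enumeration of the
permutation distribution of the rank sum (midranks under ties), which is
exact; large samples use the continuity-corrected normal approximation,
matching `wilcox.test(correct = TRUE)`.

## Boundary calling

The insulation signal at bin $i$ and window $w$ is the mean of the
$w \times w$ diamond pairing the $w$ bins ending at $i$ with the $w$ bins
starting at $i+1$; with 40-kb bins and $w = 6$ the diamond spans
$\pm 240$ kb. The signal is undefined where the diamond leaves the window
or where one side is fully masked — edge bins are reported as `NA`, never
extrapolated.

Domains are called in three steps: insulation signal; candidate
boundaries as strict local minima over a $\pm 1$-bin neighbourhood
(plateaus resolved to their leftmost bin); and a statistical filter
comparing the diamond values at the candidate with the two flanking
within-domain triangles. Two details of the filter matter and were fixed
by measurement during development:

* The comparison is made on *distance-scaled* values (each off-diagonal
  divided by its mean over unmasked cells). On raw balanced values the
  diamond pools systematically longer-range contacts than the triangles,
  so distance decay alone makes every candidate "significant".
* The rank-sum p-value at a candidate is *selection-biased*: the
  candidate is an argmin of the very quantity being tested, so at
  realistic coverage (hundreds of thousands of pairs over ~100 bins)
  shallow Poisson dips inside a perfectly homogeneous block reach
  p < 0.05 (measured: noise dips p ~ 1e-2..4e-5 versus true boundaries
  p ~ 1e-25..1e-31). The filter therefore additionally requires a minimum
  insulation contrast: the scaled diamond mean must fall below
  `min_contrast = 0.75` times the scaled flanking-triangle mean, i.e. at
  least a 25% insulation drop. The default separates the two measured
  populations by more than an order of magnitude on either side and is
  deliberately not placed between them at the midpoint: a weakened
  boundary at permeability 0.55 over enrichment 3 still shows a ~80%
  drop and remains callable, while noise dips rarely exceed 15%.

Consensus TADs aggregate calls across window sizes 3..15: a domain is
retained only when its exact `(start, end)` pair recurs in at least 40%
of the window sizes (inclusive, so 6 of 13 is kept and 5 of 13 dropped).
Identity of *both* edges is required. Boundary displacement between two
consensus sets is measured at the boundary nearest a stated anchor, with
absence declared when no interior boundary lies within 500 kb.

## 4C-seq quantification

Profiles are ordered restriction-fragment signals around a viewpoint.
Smoothing is a running mean over 11 fragments, truncated at profile edges
(the first fragment averages 6 values). Normalisation scales the profile
so the total within ±5 Mb of the viewpoint equals $10^6$; the target
constant is arbitrary — ratios and clustering are invariant to it — and
only the span matters. Domain ratios report
$100 \cdot S_a / (S_a + S_b)$ with fragment membership by midpoint and an
optional exclusion interval (e.g. the gene cluster itself) removed before
summation. Region panels are quantified with BEDTools-intersect
semantics: any-overlap on half-open intervals, so an abutting fragment
does not count. Cumulative curves shift fragment midpoints so the
viewpoint sits at offset 0 and accumulate signal in genomic order;
clustering interpolates curves onto a common 10-kb grid, rescales each to
its final value (relative cumulative frequency), and applies Ward's
minimum-variance linkage to the Euclidean distance matrix.

Two stated defaults resolve open choices: ratios are computed on raw
(unsmoothed) values, with smoothing available explicitly; and the ±5-Mb
normalisation window does not exclude viewpoint-proximal fragments.

## In silico alleles and liftover

An edit script is an ordered, non-overlapping list of deletions and
insertions on a backbone chromosome; deletion alleles carrying reporter
cassettes are deletions with a replacement `inserted_length` (N-filled
when the cassette sequence is not known). Building the mutant sequence
also yields an exact block-wise coordinate map; positions in deleted
(inserted) material have no image and lift to `NA`. All coordinates are
0-based half-open; printed 1-based inclusive coordinates are converted on
ingestion. Matrices computed on a mutant genome are reframed onto the
wild-type grid for comparison: wild-type bins with no mutant image are
dropped and masked (the same bins are masked in the wild-type matrix
before balancing), and bins straddling a breakpoint are refused unless
block offsets are bin-size multiples — whole bins are removed, never
partially lifted.

## The synthetic locus

The generator states a 3-Mb cis window at 40-kb bins holding a 720-kb and
an 880-kb contact block separated by a 2-bin (80-kb) boundary block —
loosely the geometry of a two-TAD limb locus — with expected Hi-C counts

$$\mu_{ij} = L \, b_i b_j \,(1+|i-j|)^{-\alpha}\, T_{ij},$$

where $T_{ij}$ is the within-block enrichment (default 3) inside a TAD,
the boundary permeability $\rho$ (default 0.1) between the two TADs, and
1 elsewhere; $\alpha = 1$ is a typical cis decay exponent and $L$ scales
the expected total to the coverage (default $2.5 \times 10^5$ pairs).
Counts are Poisson; overdispersed real libraries are not emulated, so a
green recovery test establishes correctness of the estimators under the
stated model, not robustness to biological replicate variance, nor to
features the generator omits (loops, compartments, mappability
structure). 4C profiles decay as $(1+d)^{-\gamma}$ with $d$ in kilobases
($\gamma = 1$; measuring $d$ in bases would concentrate essentially all
signal on the viewpoint fragment, which real 4C does not), carry Gaussian
enhancer peaks, and are Poisson-sampled at the stated depth. When a
cross-domain fraction is planted explicitly, the opposite-domain
expectation is rescaled so the expected leakage is exact — this is the
quantity the domain ratio must recover within binomial sampling error.

Deletion alleles collapse coordinates through the edit script. Partial
boundary deletions escalate permeability by the stated rule
$\rho' = \rho + (1-\rho) f$ with $f$ the deleted fraction — a modelling
stand-in for the empirical observation that larger deletions leak more —
and deleting the full boundary block fuses the two TADs into one
(truth labelled fused). Every sampling routine derives its stream from
the spec seed and restores the caller's RNG state.

# Numerical choices and degenerate inputs

* ICE: non-convergence returns the last iterate with a `converged = FALSE`
  attribute and a warning, never an error; an all-masked matrix errors.
* Rank-sum: all-tied samples give p = 1; enumeration is used whenever
  $\binom{n}{n_x} \le 2 \times 10^5$.
* Insulation windows larger than half the extent are refused.
* Consensus with no domain surviving the threshold returns an empty TAD
  table, not an error; `boundary_shift` then reports `"absent"`.
* Matrix subtraction refuses unnormalised inputs and mismatched grids.
* The midpoint of an even-length fragment is `floor((start + end) / 2)`,
  consistent between Hi-C binning and 4C membership.

# Known limitations

The caller is single-resolution TopDom-style; directionality-index or
arrowhead callers, nested sub-TAD modelling and trans contacts are out of
scope. The synthetic model is a block model, not a polymer simulation;
CTCF orientation is not modelled. Deposited-data contact-ratio targets
(11/30/39% across the allelic series) require the original sequencing
data and are not reproduced by the synthetic world — the acceptance suite
covers the qualitative counterpart (boundary present / weakened / absent)
and the quantitative recovery of planted parameters.
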