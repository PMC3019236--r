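---
title: "Methods: pooled BAC hybridisation anchoring, from signals to gene space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled BAC hybridisation anchoring, from signals to gene space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolanchor)
```

This vignette documents the models, conventions and numerical choices
behind `poolanchor` — the reasoning a maintainer or reviewer needs, in
one place. The package analyses three-dimensional pooled BAC library
screens: the minimal tiling path (MTP) of a chromosome is distributed
over plate, row and column pools, the pools are hybridised to an
expression microarray, and positive pools are deconvolved back into BAC
addresses for each probe, anchoring genes onto the physical map. Two
downstream layers — comparative genomics against a related genetic map
and an ortholog table, and gene-space statistics over deletion bins —
reuse the anchored loci.

## Signal model and normalisation

The observed intensity of probe $i$ in pool $j$ is modelled as

$$y_{ij} = b_{ij} + \sum_{B \in j,\; g_i \in B} s_0\,\bigl(1 - d(\rho_i)\bigr)\,a_B,$$

background plus one contribution per pool member BAC $B$ carrying the
probe's gene $g_i$: a base signal $s_0$, attenuated according to the
probe–target identity $\rho_i$, and scaled by the BAC's abundance $a_B$
in the pool (hundreds of BACs per pool cannot be kept equimolar).

Normalisation is two median-scaling steps. Step 1 divides each value by
the median of its own pool, removing pool-to-pool differences in overall
hybridisation level; after it, every pool median is 1. Step 2 divides
each value by the median of its own probe row; after it, every probe
median is exactly 1 while pool medians move only marginally (a probe is
positive in at most a handful of its 60 pools, so probe medians are
background-dominated). A defensible alternative reading of "the median
corresponding to the pool type" would be one shared median per *axis*
(3 medians instead of 60); we normalise per pool because the stated goal
is comparable values *for each pool*, which per-axis medians cannot
deliver when pools differ in amplification. Zero medians (an all-zero
pool or probe) abort with the offender named — a matrix without
background cannot be median-normalised meaningfully, and the scoring
functions accept raw matrices for that case.

## Positive-pool scoring

**Automated.** Per probe and axis, the threshold is
$\mathrm{mean} + k\cdot\mathrm{SD}$ over that axis's pools, with
$k = 2.8$ (plate), $2.5$ (row), $3.0$ (column); pools strictly above it
are positive. The step is repeated twice more: called positives are
deleted from the mean/SD computation (not from candidacy — they stay
called), the threshold is recomputed, and new positives are added. Three
passes let a moderate spike emerge once a dominant one no longer
inflates the SD. Conventions the source description leaves open, fixed
here and recorded in the audit attribute: the SD is the sample SD
($n-1$; a `sd_type` argument exposes the population variant), and ties
at the threshold are negative (strict inequality — with SD = 0 an
all-equal axis yields no calls).

This scheme has a hard geometric limit: a single spike among $n$ pools
is detectable only if $k < (n-1)/\sqrt{n}$, i.e. at least 10 / 9 / 11
pools on the plate / row / column axis for the default multipliers, and
two equal spikes on one axis need roughly twice that. The generator's
default geometry (20/16/24, below) satisfies both; miniature geometries
cannot, which is why the hand-built test fixtures that use 3-pool axes
pass smaller `k` values explicitly.

**Boxplot.** Positives are values above `Q3 + 1.5·IQR`, with quartiles
by linear interpolation (type 7, R's default; exposed as an argument).
The method is less stringent than the automated one, so the pipeline
keeps its calls only when they resolve onto two to three overlapping
BACs — the most self-confirming pattern.

**Semi-automated and manual completion** handle probes with missing
coordinates. A probe with five positives in a 2/2/1 pattern across the
axes is accepted iff exactly one pair of the implied wells holds two
overlapping BACs (both addresses assigned); a probe with two positives
on two axes is accepted iff exactly one value of the missing axis yields
an occupied well. Both rules are deliberately unique-solution rules:
zero candidates means undetectable, several means ambiguous, and
neither produces a call. The original manual inspection criteria are not
recoverable from any written description; "unique candidate well" is our
operationalisation, and it is applied mechanically.

Method precedence in the pipeline is automated > boxplot >
semi-automated > manual; the first method that resolves a probe wins and
later calls for the same probe are dropped (all calls remain in the
per-method tables).

## Deconvolution and repeat filtering

For each probe, the positive pools define per-axis coordinate sets; the
Cartesian product defines candidate wells. The resolver searches subsets
of the occupied candidate wells of size 1–3 whose coordinate projections
reproduce the positive sets exactly and whose BACs are mutually
overlapping on the map, preferring the smallest size (a unique well
beats a pair explaining the same pools) and requiring uniqueness at that
size. Everything else is unresolved with a reason
(`missing_axis`, `ambiguous`, `no_consistent_combination`, ...), and a
combinatorial guard marks probes whose positives imply more than 2000
wells — repeat-like behaviour — rather than enumerating them. The unit
and acceptance tests check this resolver against brute-force subset
enumeration over *all* map BACs on hundreds of random small instances.

Repeat probes are flagged by local alignment against a repeat library:
Smith–Waterman with match +1, mismatch −1, gap −2 (linear), flag iff the
best-scoring alignment reaches ≥ 80% identity (matches / alignment
columns) over ≥ 45 columns. The scoring scheme is a package choice (the
rule originates from BLASTN practice, whose parameters differ); the
+1/−1/−2 defaults are the simplest scheme under which the 80%/45 nt rule
is meaningful, and all three scores are arguments. The DP is implemented
in-package with a `cummax` row recurrence (linear gaps make the within-row
dependency a running maximum); `Biostrings::pairwiseAlignment` serves as
an independent oracle in the tests. One caveat is inherent: when several
distinct alignments share the optimal score, "the best alignment" is
ambiguous, and two correct aligners can report co-optimal alignments
with different column counts whose identities straddle the 80%/45
boundary. The acceptance test therefore demands exact score agreement on
every pair and flag agreement whenever the optimum is unambiguous, and
verifies decision-consistency on the (rare) ties.

Addresses merge into loci: mutually overlapping BACs of one probe are
one locus; disjoint placements of one probe are separate loci flagged
`duplicated` (multi-copy genes). A locus inherits the deletion bin of
its contig; conflicting bins within a locus violate a map invariant and
abort.

## Comparative layer

Synteny requires only placement on the orthologous chromosome —
order-free by definition. Collinearity uses synteny blocks: because the
within-bin order of loci is unknown, loci are sorted by bin (in
chromosome order) and the largest subset with non-decreasing reference
positions (longest increasing subsequence, $O(n^2)$ DP, earliest optimum
on ties) defines the consistent assignment; each bin's block is the
[min, max] reference interval of its kept loci, and a locus is collinear
iff its position falls inside its own bin's block. The LIS rule is our
formalisation of "inferring the virtual order from the reference" — any
rule must decide which of two mutually inconsistent loci to trust, and
maximising the number kept is the natural non-parametric choice. The
collinear set is invariant under order-preserving transforms of the
reference positions (tested).

Chi-square uniformity tests construct their expected values: the global
proportion $\bar p = \sum o_i / \sum t_i$ applied to each bin's total
$t_i$ (counts for percentage uniformity, Mb of assigned contigs for
density uniformity), Pearson $X^2$ with $\mathrm{df} = \text{bins} - 1$.
Published p-values for such tests are not exactly reproducible without
knowing the original category structure and df convention; the
construction here is stated precisely, cross-checked against
`stats::chisq.test` with rescaled proportions, and warns when an
expected count drops below 1. Correlation tests delegate to
`stats::cor.test`, and the two-sample comparison is Welch's t-test
(`stats::t.test`, two-sided) — variance equality between groups is not
assumable.

## Gene space

Density is loci per Mb of contigs assigned to the bin — assigned
contigs, not full bin size, because only the covered fraction was
screened. Normalised densities divide by the mean of the unrounded
per-bin densities (mean exactly 1 by construction). Distance to the
centromere is measured to bin midpoints, in Mb.

Gene islands: two loci are joined when they share a BAC, sit on
overlapping BACs, or their BAC intervals lie on the same contig with
nearest edges closer than 150 kb; islands are connected components of
size ≥ 2 (transitive closure — a chain of pairwise-close loci is one
island). Separation is measured between BAC-interval edges because the
BAC is the unit of resolution of the assay; inter-contig gaps always
break islands since the physical distance across a gap is unknown.
Island membership is monotone in the gap threshold (partition
refinement; tested).

Extrapolation projects observed densities onto user-supplied full bin
sizes and rescales to a target total; full sizes are an input because
assigned-contig lengths are the only certain lengths. The
tandem-correction estimate is the floored deficit
$1 - \text{norm}_\text{obs}/\text{norm}_\text{ref}$ against a reference
density profile; no simple formula reproduces previously published
missed-fraction figures exactly, so the operation reports this stated
formula's value rather than imitating an unknown derivation.

## The synthetic generator

`sim_config()` defaults define the study conditions the package is
validated under: a 995 Mb chromosome, centromere at 0.4 of its length,
MTP coverage 0.82 with 0.30 pairwise BAC overlap, ~157 kb BACs tiled
into 200 contigs (~7 400 BACs), pooled 20 × 16 × 24; 800 gene probes
with probe–target identity from a truncated normal (mean 88%, SD 5,
range 75–100 — matching the observation that detected genes cluster
near 90% identity and undetected ones in the low 80s); attenuation 0 at
100% identity, a per-probe draw from [0.73, 0.99] at 90%, linear to
total loss at ≤ 80% (the simplest curve through the reported anchor
points); log-normal per-BAC abundance with CV 0.3 and log-normal
background with median 1 (a modelling choice — no background
distribution is published; parameters are exposed); a twofold
centromere→telomere density gradient; island probability rising 0.25 →
0.5 from centromere to telomere (≈ 0.39 overall under the gradient
weighting); island clusters of 2–4 genes spaced < 100 kb; 2% duplicated
placements; 5 injected repeat probes.

Two generator choices deserve emphasis. First, the geometry: a
"desk-scale" miniature (a few plates and rows) is mathematically
incompatible with the automated-scoring thresholds (see the
detectability bound above) — single positives would be undetectable on
two axes and the noiseless-identifiability property could never hold.
The defaults therefore keep the study-scale geometry, which R handles in
seconds. Second, isolation: island membership is decided per gene at a
gradient-weighted position (so the realised fraction is binomial around
the requested curve), and *isolated* genes are placed with enough
clearance (`isolation_bp`, default 150 kb + 2.5 BAC lengths) that their
BAC footprints cannot merge into chance islands; without this, at
realistic gene density, nearest-neighbour distances alone would make
most genes "islands" and no requested fraction could be recovered.
Ground-truth island labels are recomputed from the realised BAC
footprints by a positional sweep — an independent implementation against
which the graph-based detector is tested; clusters truncated by an MTP
gap or contig edge are labelled by what was realised, not what was
requested.

What the generator does **not** emulate: sequence-level BAC content
(probe sequences are random 60-mers except for injected repeat probes),
dye and spatial chip artefacts, cross-hybridisation between paralogous
gene probes, well-level contamination, and real marker maps (reference
positions for synteny recovery are monotone transforms of physical
position plus noise). Passing recovery tests therefore demonstrates the
correctness of the analysis chain under the stated statistical
structure, not robustness to every artefact of real arrays.

## Problem sizes and determinism

The test suite runs the full generator at study scale (≈ 7 400 BACs, 800
genes) for the noiseless-recovery check and for 20-seed gradient/island
recovery loops; deconvolution is cross-checked against brute force on
500 random 27-well instances and the aligner against an independent
implementation on 200 random pairs — sizes chosen so the whole suite
completes in a few minutes while keeping every Monte-Carlo assertion at
20 seeds. All randomness flows from explicit seeds; `run_pipeline()`
with the same configuration and seed writes byte-identical reports, and
`scripts/acceptance.R` reseeds every simulation from its `--seed`
argument.

## Known limitations

- Deconvolution resolves at most three mutually overlapping BACs per
  locus; genes present at many loci (large families) are unresolvable by
  design and surface as `ambiguous` / `too_many_positive_pools`.
- The attenuation curve is piecewise linear between three anchor points;
  real hybridisation kinetics are smoother and sequence-dependent.
- Collinearity depends on the LIS tie-breaking when reference positions
  tie exactly (common in low-resolution genetic maps); the earliest
  optimum is kept.
- The chi-square uniformity construction fixes one of several defensible
  df/category conventions; its p-values are comparable across runs of
  this package but not necessarily to other implementations.
- Published full deletion-bin sizes are not bundled; extrapolation to
  whole-bin gene counts runs only when the user supplies them.
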