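---
title: "Methods: structure aggregation, gene-space correction and SV arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure aggregation, gene-space correction and SV arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panstruct)
```

This vignette is the package's own account of its science: the models and
rules it implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
published protocol left the design open.

## The admixture model and its EM estimator

A sample's dosage at a SNP counts alternate alleles, `g ∈ {0, 1, 2}`.
Under the admixture model each of the two alleles is drawn independently
from one of K ancestral groups with probabilities `q_i` (the sample's
ancestry vector, a point on the simplex), and an allele from group k at
SNP j is the alternate with probability `f_kj`. Hence

$$g_{ij} \sim \mathrm{Binomial}\!\left(2,\; p_{ij}\right),\qquad
  p_{ij} = \sum_k q_{ik} f_{kj},$$

and the log-likelihood is
$\sum_{ij} g_{ij}\log p_{ij} + (2-g_{ij})\log(1-p_{ij})$, missing cells
contributing nothing (complete-case per cell). `admix_em()` maximizes this
by plain EM: the expected number of alleles a sample inherited from group
k updates Q, the expected alternate-allele share per group updates F. The
external tool the protocol used maximizes the same likelihood with a
block-relaxation accelerator; at desk scale the accelerator buys nothing,
and EM's guarantee — a non-decreasing log-likelihood trace — is asserted in
the tests (to a 1e-6 numerical tolerance, since F is clamped to
`[1e-6, 1-1e-6]` for a finite likelihood).

Initialization is seeded: Q from a flat Dirichlet, F as the per-SNP sample
frequency plus a uniform ±0.05 offset drawn **per ancestral group**, not
per SNP. The per-group choice makes the whole fit exactly equivariant
under SNP-column permutation — permuting the SNPs of the input permutes
nothing that matters, and the final log-likelihood is identical to machine
precision — which would fail with per-SNP jitter.

Convergence: the default tolerance (1e-4 log-units improvement) is strict
for EM's slow tail; fits that hit the iteration cap return
`converged = FALSE` with a warning rather than an error, because the
estimates are typically excellent long before (parameter recovery on the
reference panel reaches RMSE < 0.02 within a few hundred iterations).
Tests cap iterations accordingly.

## Aggregating runs into modes

Independent runs at the same K label groups arbitrarily (label switching)
and may converge to genuinely different solutions (modes) — in the real
analysis, alternative refinements such as whether `XI-1A` or `GJ-trop`
splits. The aggregation procedure:

1. **Alignment.** The permutation of one run's columns minimizing the
   summed squared difference to a reference run is found exactly by
   optimal assignment on the K×K column-distance cost matrix
   (`clue::solve_LSAP`). This is the least-squares objective the CLUMPP
   tool approximates heuristically; at K ≤ 15 the exact solution is cheap,
   and the tests verify it against exhaustive search over all K!
   permutations for K ≤ 6.
2. **Run distance.** After alignment, the per-cell root-mean-square
   difference, normalized by its maximum for simplex rows
   (`sqrt(Σ(a-b)² / 2n)`), so the value lies in [0, 1] and reads as a
   per-cell scale. The protocol names no metric; this normalization makes
   the tree-cut threshold interpretable.
3. **Clustering and the cut.** Average-linkage hierarchical clustering of
   the runs, tree cut at 0.1 — i.e. runs whose aligned Q matrices differ
   by more than ~10% RMS per cell do not share a mode. The linkage and cut
   are this package's choices (the protocol states neither); 0.1 sits an
   order of magnitude above the within-mode noise of the planted
   ensembles and well below between-mode separation.
4. **Outliers and averaging.** One-element clusters are discarded as
   outlier runs — the published rule. Each surviving cluster is averaged
   cell-wise after aligning every member onto the cluster **medoid** (the
   member with the smallest summed distance to the rest); the medoid, not
   the first run, so the result cannot depend on run order. Averaged rows
   remain on the simplex by construction. The largest cluster is the
   primary mode `"K"`, further modes `"K.1"`, `"K.2"`, … in size order,
   matching the convention that `9.1` names the secondary solution at
   K = 9.
5. **The ladder.** Columns of the averaged Q at K+1 are matched to columns
   at K by Pearson correlation across samples (scale-free; ties broken
   toward the larger mean proportion). A parent matched by two children is
   a split, and children extend the parent's name (`XI-1B` → `XI-1B1`,
   `XI-1B2`). How exactly the original analysis combined columns across K
   into the final grouping is under-specified; this correlation ladder is
   one faithful reading, and the tests verify it recovers planted
   hierarchies and agrees with assignment-based matching where the match
   is unambiguous.

## Membership calls and representative selection

The 0.65 rule: a sample whose largest component reaches 0.65 belongs to
that subpopulation; otherwise, if the components of one major variety
group (cA, XI, GJ) sum to at least 0.65 the sample is admixed within that
group (`XI-adm` etc., ties to the largest sum, evaluated in the fixed
order cA, XI, GJ); otherwise fully admixed. The source text says both
"exceeding 0.65" and "≥ 0.65"; `>=` is applied uniformly — the boundary is
measure-zero on real data, and internal consistency matters more. For any
threshold above 0.5 at most one direct call can fire (simplex rows sum
to 1); this is asserted, not assumed.

"PCA of the IBS distance matrix" is implemented as classical
multidimensional scaling (principal coordinates): double-center the
squared distances, take the top five eigenvectors scaled by the square
roots of their eigenvalues. That is the only principled reading of a PCA
applied to a distance matrix; for Euclidean input it reproduces pairwise
distances exactly (tested to 1e-8). Axis signs are fixed (largest-
magnitude loading positive) so runs are reproducible. The IBS distance is
`1 − mean((2 − |g_i − g_j|)/2)` over SNPs genotyped in both samples.

A group's representative is its member nearest (Euclidean over the five
axes) to the group centroid — the mean coordinate of **all** members, so
unavailable accessions still shape the centroid but cannot be chosen. Seed
availability is an input flag, not inferred: germplasm availability is an
external fact. Ties break lexicographically by sample id.

## Assembly arithmetic and the gene-space correction

`contig_n50()` is the textbook statistic (smallest length whose
equal-or-longer contigs cover half the assembly); `gap_count()` counts
maximal N-runs; `table_summaries()` takes means rounded half-up to two
decimals, matching the printed tables' formatting (R's default
round-half-even would differ on boundary values).

The adjusted BUSCO score is not given as a formula in the source, only as
recalculated values. The inference: 13 of the 1,440 benchmark genes are
absent from every assembly evaluated **and** from outgroup cereal genomes,
so they cannot be found in this lineage and deflate every raw score;
rescaling by `1440/(1440−13)` and rounding half-up to two decimals
reproduces all twelve printed (raw, adjusted) pairs exactly — the printed
table is the oracle that validates the inferred formula, and the test
suite asserts all twelve pairs, not just the examples.
`universal_missing()` implements the two-stage set logic (intersection of
per-assembly missing sets, then removal of anything present in an
outgroup) on arbitrary panels.

Two printed numbers are knowingly not used as targets: the text's 47.66%
mean total TE content (the sixteen printed per-genome totals average to
47.48 — likely a length-weighted mean in the source) and the 31.91 Mb
maximum contig N50 in the background text (the per-assembly table says
30.91 Mb; the table is taken as authoritative).

## Genome size from the k-mer spectrum

Canonical (strand-collapsed) k-mers are counted across the reads and their
depth histogram built. Error k-mers pile up at depth 1–2; the estimator
excludes this limb up to the first local minimum, takes the remaining
depth peak, and returns total k-mers over peak depth.

One numerical choice matters. The effective k-mer coverage is
`cov · (read_len − k + 1)/read_len`, which falls between integer depths,
and the histogram's bin counts are overdispersed because adjacent k-mers
share reads — so the integer mode can sit one or two bins off the true
peak, a 3–5% error that breaches the 2% recovery contract. The peak is
therefore estimated as the count-weighted mean depth of the coverage
component (which is near-symmetric, so its mean estimates its peak), with
the error limb excluded from both the peak and the total. On error-free
20×/40× reads from a 100 kb genome this recovers the size to 0.2–0.4% and
is invariant to doubling coverage. The full generative model of the
original estimation program (heterozygosity, repeat classes) is out of
scope; real heterozygous or repeat-rich genomes would need it.

## Structural-variation arithmetic

Assemblies are fragmented into fixed-length pseudo-reads at 10×
redundancy. The original tool chain cuts non-overlapping windows; how 10×
redundancy was achieved is not stated, so it is implemented as ten
phase-shifted non-overlapping tilings (offsets of `read_len/redundancy`),
which reproduces 10× equivalence deterministically — every interior base
is covered 9 or 10 times, a property the tests check base-by-base.
Terminal windows shorter than a tenth of the read length are dropped
(contigs shorter than that are emitted whole with a warning).

Only insertions, deletions and tandem duplications up to 25 kb are kept —
"up to" read as inclusive (a 25,000 bp record passes, 25,001 is dropped).
Affected reference sequence merges DEL/DUP intervals before summing
(overlap counted once — the source does not state whether it merged;
merging is adopted and documented) and adds inserted lengths, whose
reference footprint is a single anchor base. The TE-related fraction
overlaps the merged intervals with the reference's TE track and adds
inserted bases flagged TE-derived; insertions without flags count as
non-TE, logged once — classifying inserted sequence against a TE library
is external to this package.

The toy detector (`naive_pair_sv`) stands in for long-read mapping plus SV
calling at desk scale only: k-mers unique in both genomes are anchored,
the collinear chain extracted (longest increasing subsequence), and each
inter-anchor gap classified by its reference-side and query-side lengths,
with a duplicated-adjacent-window check separating tandem duplications
from plain insertions. Anchors are thinned to one per 10 bp — both gap
sides grow equally, so classification is unchanged and breakpoint blur
stays below the anchor size. It recovers ≥ 90% of planted events ≥ 200 bp
spaced ≥ 2 kb with correct types; it is not a caller for real genomes
(no inversions, no translocations, unique-anchor density assumed).

## What the generators emulate — and what a green test establishes

`simulate_genotypes()` draws per-population allele frequencies from the
Balding–Nichols distribution (`Beta` with mean p and variance F·p(1−p))
around uniform ancestral frequencies, then dosages binomially given each
sample's ancestry. It emulates differentiated subpopulations and planted
admixture, with FST defaulting to 0.15 — a fixture choice in the realistic
range for rice subpopulations, not a published value. It does **not**
emulate linkage disequilibrium, coalescent genealogy, ascertainment of
SNP panels, or missingness structure; a green recovery test certifies the
estimator and the aggregation logic, not performance on real 3K-panel
data.

`simulate_run_ensemble()` perturbs a base Q row-wise with Dirichlet noise
(concentration `1/noise_sd²`, so rows stay on the simplex by construction
— additive Gaussian noise would leave it), permutes columns to plant label
switching, and can plant a second mode by merging the two closest groups
and re-splitting the largest — mirroring the split-ambiguity mechanism
described for the real runs. `simulate_toy_genome_pair()` plants
non-overlapping events left-to-right and emits a TE track covering a
configured fraction of them, giving exact ground truth for the SV and TE
arithmetic. `simulate_reads()` places uniform forward-strand reads with
independent substitution errors — no indel errors, no quality profile.

All generators refuse to run unseeded, and identical seeds give identical
output; the pipeline manifest records the seed and artifact checksums, and
a rerun is byte-identical.

## Degenerate inputs and tie-breaks

Empty interval sets have zero total; empty SV sets zero affected bp.
K = 1 EM returns the analytic optimum (F = mean dosage / 2). Runs at a K
with no stable mode (all singleton clusters) raise "no stable mode" — on
synthetic panels this happens, correctly, for K above the planted depth.
Ties: assignment ties are broken deterministically by the solver;
ladder-match ties toward the larger mean proportion; representative ties
lexicographically by id. Distance matrices must be symmetric with zero
diagonal; samples sharing no genotyped SNPs are an error naming the pair.

## Known limitations

Desk scale throughout: the EM is dense R/BLAS (fine to ~10⁵×10⁴), the
k-mer counter holds k-mers as strings in memory, the SV detector assumes
unique anchors and two collinear single-contig genomes. The BUSCO
correction assumes the excluded-gene count is right for the lineage; the
k-mer estimator assumes near-homozygous, repeat-poor genomes; the TE
fraction undercounts when insertions are unclassified.
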