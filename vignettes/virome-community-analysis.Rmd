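---
title: "Methods: vOTU community analysis with a richness-conserving null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vOTU community analysis with a richness-conserving null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizovirome)
```

## The problem

Bulk metagenomes from plant root zones carry viral contigs alongside the
microbial ones. After the upstream steps (assembly, viral prediction, quality
control, read mapping) have produced a catalog of viral operational taxonomic
units (vOTUs) and per-sample mapping coverage, the ecological questions
remain: which vOTUs are present where, how diverse are the communities, and
do plant phenotype and soil compartment (bulk sediment, rhizosphere, root)
structure them? `rhizovirome` implements that downstream layer for a crossed
design of two plant phenotypes (short and tall growth forms of a salt-marsh
cordgrass) by three compartments with four replicates — 24 samples.

The package deliberately consumes *tabular* outputs of the upstream tools
(coverage summaries or `samtools depth` streams, pairwise similarity tables,
gene annotation tables, host predictions) and never runs alignment, assembly
or HMM searches itself.

## Presence, dereplication and abundance

**Presence.** A vOTU is present in a sample when mapping covers at least 75%
of its contig length (breadth of coverage ≥ 0.75, inclusive). Breadth is the
fraction of positions with depth ≥ 1; the threshold is a conservative guard
against spurious recruitment of reads to conserved subsequences.

**Catalog.** Contigs shorter than 5,000 bp are removed (inclusive bound at
5,000). Dereplication into populations uses the community convention for
dsDNA viruses — 95% average nucleotide identity over 80% alignment coverage —
applied greedily longest-first: sequences are visited by decreasing length
(ties by identifier) and join the first cluster whose *representative* they
match at both thresholds, else found a new cluster. The founding (longest)
member is the representative. We interpret the 80% coverage as coverage of
the shorter sequence (the CD-HIT convention); both thresholds are inclusive
and configurable. Computing the identities themselves is out of scope — the
function consumes a precomputed pairwise table.

**Abundance.** TPM: per sample, each vOTU's mapped-read count is divided by
its length in kb, and the rates are scaled to sum to $10^6$. By default every
vOTU with at least one mapped read enters the denominator, because presence
calling and abundance estimation are separate steps; `mask_absent = TRUE`
instead zeroes sub-threshold vOTUs *before* normalization. Both behaviors are
exposed because coverage summaries alone cannot distinguish which convention
produced a given published table.

`read_depth_file()` consumes the three-column `samtools depth` dialect
(1-based positions; zero-depth rows may be omitted). Contig lengths must come
from a length table or FASTA — never from the maximum observed position. A
depth stream does not carry the mapped-read count, so the reader estimates it
as `round(sum(depth) / read_length)`; supply a true coverage summary when
exact counts matter.

## Diversity

Richness is the per-sample presence count. The sample-accumulation
(rarefaction) curve averages cumulative union sizes over 100 uniformly random
sample orderings; the mean curve is non-decreasing and ends at the total
number of vOTUs seen anywhere.

Pairwise richness comparisons use the two-sided Mann–Whitney test. With four
replicates per cell the normal approximation is unreliable, so the exact null
distribution of U is used whenever both groups have ≤ 8 observations and no
ties; otherwise the normal approximation with tie and continuity corrections.
Raw p-values are reported by default (no correction across the pairwise
tests), with Holm correction available as a flag.

Beta diversity uses Bray–Curtis dissimilarity on TPM,
$BC(x,y) = 1 - 2\sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)$. A pair of
all-zero samples is undefined under the formula; it is reported as 0 with a
warning rather than crashing a pipeline. Ordination is global non-metric
multidimensional scaling (Kruskal stress-1, iterative monotone regression,
delegated to `vegan::monoMDS`) with 20 restarts — the first from a metric
(principal-coordinates) start, the rest random — keeping the lowest-stress
solution; defaults are `max_iter = 300`, stress tolerance `1e-6`. PERMANOVA
is computed directly on the dissimilarity matrix (among/within sums of
squared dissimilarities, pseudo-F), with the p-value from free uniform label
permutations: $p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$,
999 permutations by default, no strata.

## Sharing classes and the null model

The co-occurrence analysis concerns vOTUs found in **two or more samples**.
Each such vOTU is classified by the set of phenotypes its samples span
(`short-only`, `tall-only`, `both-phenotypes`) and by the set of compartments
(three exclusive classes, three pairwise, `all-three`).

The null model asks what those class counts would look like if vOTU
identities were exchangeable: in each replicate, every sample is reassigned a
uniformly random subset of the full vOTU catalog — including vOTUs observed
only once, since the ≥ 2-sample filter must be allowed to act on the
randomized data too — of size equal to that sample's observed richness. The
multi-sample filter and classification are then recomputed. Conserving
per-sample richness is the strictest reading of "conserving only richness"
for a design in which each sample belongs to one phenotype × compartment
cell; an alternative `per_cell` mode pools occurrences within each cell and
redraws that many (vOTU, sample) incidences cell-wide, conserving cell-level
incidence totals instead.

Expected class proportions are pooled across replicates (total class counts
over total multi-sample counts) rather than averaged per replicate: a
replicate whose multi-sample set is empty has no defined proportions, while
the pooled estimator is always defined and coincides with the per-replicate
average at study scale. A Pearson chi-squared goodness-of-fit test compares
observed counts to the pooled proportions scaled to the observed multi-sample
total (phenotype df 2; compartment df ≤ 6); classes expected and observed
zero are dropped from the degrees of freedom, an observed count in a
zero-expectation class is flagged as an infinite statistic, and expected
counts below 5 raise a warning. Per-replicate class counts are returned so
the Monte-Carlo error is auditable.

`exact_null_expectations()` is the package's own independent oracle: it
enumerates every combination of per-sample subsets (refusing instances above
$10^6$ combinations) and returns exact expected class counts. The test suite
verifies the Monte-Carlo null against it within three standard errors at
10,000 replicates.

## Annotation filters

Significant HMM hits require bit score **strictly above** 30 ("above 30") and
e-value **at or below** 0.01 ("cutoff of 0.01"). A metabolic gene qualifies as
an auxiliary metabolic gene (AMG) candidate only if it is interior — not
among the first or last `flank` genes of its contig — and its `flank` nearest
neighbors on both sides are viral-annotated. `flank = 1` is the minimal
faithful reading of "surrounded by viral proteins"; wider windows are a flag.
The rule is symmetric, so reversing gene order within a contig leaves the
flagged set invariant (a property test).

Host predictions (one order-level host per vOTU at most) are joined to a
table of microbial orders with biogeochemical roles (sulfur oxidation,
sulfate reduction, iron oxidation, nitrification); summaries count unique
phyla and orders, orders with at least one role, and the fraction of hosted
vOTUs targeting functional taxa. Per phenotype × compartment cell, a vOTU
counts as present if found in at least one of the cell's samples, and the
reported percentage is hosted-over-present.

## The synthetic-data generator

No sequencing data ship with the package; the generator produces inputs with
the statistical structure the analysis assumes, so every stage is testable
end to end.

Per vOTU: a log-uniform contig length on [5, 60] kb (heterogeneous lengths
exercise the TPM length correction); with probability `phenotype_fidelity`
(default 0.8) a restriction to one phenotype; a compartment sharing class
drawn from weights that default to
(bulk 0.10, rhizosphere 0.05, root 0.05, bulk+rhizosphere 0.20,
rhizosphere+root 0.30, bulk+root 0, all-three 0.30); and independent
occupancy of each eligible sample with probability 0.35. The zero weight on
`bulk+root` encodes the proximity gradient — bulk and root share viruses only
via the rhizosphere — and a repair step enforces it for `all-three` vOTUs
whose random occupancy would otherwise realize exclusive bulk+root sharing.
Compartment proximity is encoded as class weights rather than a spatial
model because the downstream statistics are purely categorical.

Coverage: present pairs draw breadth uniformly on [0.75, 1] and
negative-binomial read counts at mean depth 5× (dispersion 0.5); absent pairs
draw breadth uniformly on [0, 0.70]. The guard gap between 0.70 and 0.75
makes ground-truth occupancy *exactly* recoverable by presence calling — a
property the tests assert. The defaults (769 vOTUs over 24 samples, mean
per-sample richness around 110) were chosen once as a realistic scale for a
soil virome study of this design; the underlying study reports no per-sample
richness or occupancy rates, so these are modeling choices, not fitted
values.

What the generator does **not** emulate: read sequences, assembly artifacts,
chimeras, uneven sequencing depth between samples, or phylogenetic
correlation between vOTUs. Passing tests therefore demonstrate correctness of
the statistics on data satisfying the stated occupancy model, not robustness
to upstream artifacts in real data.

## Numerical choices and edge cases

- Thresholds quoted as "≥ 75%" and "5,000 bp" are inclusive; bit score is
  exclusive and e-value inclusive, following their respective wordings.
- Ties in the dereplication length ordering break alphabetically by id, so
  output is deterministic.
- `mann_whitney` switches to the approximation whenever ties exist, even in
  small samples, because the exact U distribution assumes continuity.
- All-zero abundance pairs yield Bray–Curtis 0 with a warning.
- PERMANOVA requires at least two groups and a positive residual df; the
  permutation p-value can never be below $1/(n_{perm}+1)$.
- Every randomized operation takes an explicit seed and is bit-reproducible
  under it.

## Problem sizes used in tests and examples

The test suite runs the full stack at study scale (769 × 24) for the
ground-truth-recovery and power checks, uses 10,000 null replicates against
exhaustively enumerable instances (≤ 576 combinations) for the oracle
comparison, and 1,000 simulated trials for the type-I error checks of the
chi-squared and PERMANOVA tests (199 permutations each). These sizes keep the
Monte-Carlo error small relative to the 3-SE acceptance bands while the whole
suite completes in well under a minute of compute for the deterministic parts
and a few minutes overall.

## Known limitations

- The null model conserves richness only; a variant that additionally
  conserves per-vOTU occupancy frequencies (fixed-fixed) is not implemented.
- ANI computation, read alignment and viral prediction are out of scope; the
  package trusts its tabular inputs.
- The NMDS stress value and PERMANOVA p-values on synthetic data are
  properties of the generator, not reproductions of any published ordination;
  reproducing published values would require the original reads.
- `read_depth_file`'s mapped-read estimate is exact only when reads map
  end-to-end without clipping.
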