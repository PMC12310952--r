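---
title: "Clonal lineage analysis with clonetrace: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal lineage analysis with clonetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

# The problem

Heritable lineage barcodes — semi-random oligonucleotides integrated into
progenitor genomes by a transposase and read out in the transcriptome of a
droplet scRNA-seq experiment — let one ask which differentiated cell types
descend from common progenitors. `clonetrace` implements the analysis path
from raw barcode evidence to three kinds of biological statement:

1. **Clone assignment**: which cells are clonally related, inferred from
   shared integration-barcode sets.
2. **Lineage coupling**: which pairs of cell states co-occur within clones
   more (or less) often than chance, via permutation-null z-scores.
3. **Composition and stability**: what clones are made of (restricted vs
   mixed, exclusive fate classes, intersection tables), and how far a
   population drifts in expression space across time
   (scrambled-normalized PCA distance).

A synthetic-data generator with full ground truth accompanies the pipeline
so that every stage can be validated against a known answer. Its defaults
emulate a dual-progenitor cortical experiment: two radial-glia subtypes
(`RGC_1`, `RGC_2`) with strongly biased clonal output over neurons and two
astrocyte lineages (S100a11-type and Olig2-type).

# From reads to the cell-by-barcode matrix

`extract_barcodes()` trims the constant flanks around the barcode in each
read, drops inserts shorter than 37 bases, keeps only whitelisted cell
barcodes, and aggregates identical (cell, UMI, barcode) observations into
*triples* with read support. `filter_triples()` then applies the two
molecular thresholds in a fixed, documented order:

* triples need **≥ 10 reads** (PCR/sequencing noise floor), then
* cell–barcode pairs need **≥ 6 distinct surviving UMIs** (independent
  molecule support).

The order — extract, length filter, aggregate, read filter, UMI filter —
is fixed; the UMI filter counts only UMIs whose triples survived the read
filter. Both thresholds, and every in/out count, are reported in a filter
report attached to the result and echoed in pipeline logs. Flank matching
is exact substring search by default; a Hamming tolerance is available
(`max_mismatch`) but defaults to 0 because no mismatch tolerance is part of
the standard procedure. UMIs are compared as exact strings (no 1-mismatch
collapse), again because no correction step is part of the procedure.

`build_matrix()` produces the binary cell × barcode incidence matrix in
sparse form with lexicographic row/column order. Cells on the whitelist
that end up with no surviving pair are dropped and counted — with ~75%
barcode recovery, a quarter of cells are expected to be unusable for clonal
analysis, and the drop report makes that visible.

# Clone calling

Cells are clustered on **Jaccard distance** (1 − |A∩B|/|A∪B|) between
integration-barcode sets using **average linkage**, and the dendrogram is
cut at `cut_height` (default 0.5). Cells sharing the majority of their
integrations merge; two multi-barcode clones that collide on a single
barcode (Jaccard 1/3 → distance 2/3) do not.

Implementation notes that matter for reproducibility:

* The agglomeration is a weighted UPGMA written for this package: cells
  with identical barcode sets are collapsed into weighted nodes first
  (exactly equivalent, since the average-linkage distance between clusters
  is the mean over all original cross pairs), which makes the procedure
  fast at experiment scale without changing any answer.
* Ties are broken deterministically toward the clusters containing the
  lexicographically smallest cell IDs, and all distance comparisons use a
  1e-9 tolerance so that exact rational ties (Jaccard distances are
  ratios of small integers) are recognized under floating-point
  arithmetic. The result is therefore invariant to input row order, and
  the test suite holds it equal to an exhaustive-recomputation
  average-linkage oracle on hundreds of random instances.
* `cut_height` is the principal sensitivity parameter: as it approaches 0
  the partition degenerates to exact barcode-set equality; at 1 everything
  connected by any transitive similarity merges. It is recorded on the
  clone table and in the run manifest.
* Clones should be called per 10x reaction/animal: barcodes are delivered
  per embryo, and pooling animals invites inter-animal barcode collisions.
  The package does not stop you from pooling, but the simulator's
  collision model (below) shows why you should not.

Partial barcode capture (a cell observing only a subset of its clone's
integrations) is handled by the linkage itself: a cell with {B1} joins a
{B1,B2} clone at distance 0.5, which the default cut accepts. No special
subset rule is added.

# Lineage coupling

A clone is **shared** between two states when it contains at least
`min_cells = 2` cells of each. For each state pair, the observed shared
count O is compared with its permutation null: the cell→state label vector
is shuffled uniformly over **all cells jointly** (clone structure and
marginal label counts fixed — shuffling within clones or within states
would answer a different question), the count recomputed, and after
`n_perm = 10000` permutations

$$Z = (O - \mu)/\sigma$$

with μ, σ the permutation mean and (population) standard deviation.
Positive Z means lineage coupling, negative anti-coupling. The diagonal —
clones with ≥ 2 cells of one state — is the self-coupling/expansion signal
and is retained in Z, but **excluded** from the row vectors when Pearson
correlations between z-rows are computed (it would trivially inflate
similarity); for the pair (i, j), columns i and j are dropped from both
rows. Correlations therefore need at least 4 states. Pearson is the
default (an option in spirit; Spearman can be computed from `$Z` directly).
Average-linkage clustering of z-rows supplies the heatmap ordering.

Degenerate cells (σ = 0, e.g. a state with a single cell) get Z = 0 and a
`mask` entry rather than NaN. The permutation seed is a required,
recorded parameter, and `mc_se` reports the Monte-Carlo standard error of
each μ. No multiple-testing correction is applied across pairs — the
z-matrix is a descriptive map, not a hypothesis test battery.

# Composition summaries

* `clone_category_fractions()` — among clones containing an anchor group
  (e.g. astrocytes), the fractions that are pure vs mixed with partner
  groups; categories are exclusive and exhaustive, so fractions sum to 1.
* `upset_intersections()` — counts of clones per exact combination of
  present states; counts sum to the number of eligible clones.
* `classify_clone_fates()` / `exclusive_fate_fractions()` — exclusive
  classification by ordered precedence rules. The default order —
  *contains an Olig2-lineage astrocyte* > *contains an S100a11-lineage
  astrocyte* > *contains a neuron* > *progenitors only (self-renewing)* —
  reflects that astrocyte output is the rarer, more informative event; the
  rules are a plain named list and fully configurable.

Presence thresholds are deliberately split: composition uses
`presence_min = 1` (a clone "contains" a type if one cell shows it), while
coupling uses the stricter ≥ 2 rule that defines shared clones. Both are
explicit arguments. Eligibility for progenitor-clone classification
defaults to ≥ 1 cell of the focal subtype (`eligible_min`), the laxer of
the two defensible readings; it is exposed for sensitivity analysis.

# Expression statistics

`lognormalize()` is the standard depth normalization
x′ = ln(1 + 10⁴·x/colsum); every cell then satisfies
Σ(exp(x′) − 1) = 10⁴ exactly, which the tests assert to 1e-9.

`pca_distance()` measures transcriptional drift of a subtype between a
reference timepoint and later ones. PCs are computed once on the whole
(per-gene centered, standardized) matrix; the statistic uses the first 30
components. The distance D is the **mean over all cross pairs** (reference
cell × later cell) of Euclidean distance in PC space — not the centroid
distance, which would read pure dispersal as zero change; centroid mode is
available as an option. D is normalized by a scrambled distance D_s, the
same quantity computed across random half-splits of the whole dataset. A
single split is the literal minimal reading; the default averages
`n_scrambles = 20` splits for stability (`n_scrambles = 1` reproduces the
single-split behaviour). R = D/D_s ≈ 1 means "no more drift than any
random split". All-identical inputs raise a defined error rather than 0/0.
No highly-variable-gene selection is applied by default (none is part of
the statistic); standardization can be disabled.

`module_score()` is the generic binned-control gene-set score: genes are
binned into 24 equal-frequency bins by mean expression, each set gene draws
100 control genes from its bin (with replacement, seeded), and the score is
the per-cell set mean minus control mean. This is the standard formulation
of expression-matched gene-set scoring; the bin and control counts are
exposed.

# The synthetic generator

`simulate_experiment()` generates, per founding progenitor: a clone fate
category from the subtype's fate profile; a clone size; k ≥ 1 integration
barcodes drawn **with replacement from the finite library** (default 10⁵
variants), so two clones collide at the analytic birthday rate — the tests
hold the realized collision count inside the Poisson 99% interval of
choose(F·k̄, 2)/L. Member cells inherit the founder's barcode set exactly;
capture noise then enters as: a cell yields no triples at all with
probability 1 − 0.75; UMI counts per captured pair and read counts per
triple follow configurable zero-truncated distributions.

Defaults and the reasoning behind them:

| parameter | default | rationale |
|---|---|---|
| fate profile | RGC_1: 90/5/5/0, RGC_2: 16/50/0/34 (% neuron/olig2/s100a11/self-renew) | the emulated experiment's reported clone-level fate split |
| clone size | zero-truncated Poisson, mean 4.5 | the reported average clone size; the Poisson family keeps sibship sizes tight, so lineage signal is carried by composition rather than a few giant clones (an NB family with configurable dispersion is available) |
| library size | 10⁵ (≈10⁴ recovered per run) | reported library diversity and recovery |
| integrations/cell | zero-truncated Poisson, mean 2 | multiple integrations per founder are typical for transposon delivery; the true distribution is unreported, so this is a modeling choice exposed in the config |
| recovery rate | 0.75 | reported fraction of cells with barcodes |
| UMIs/pair | zt-NB, mean 15, shape 15 | high enough that a captured pair rarely dies at the 6-UMI filter, as expected for a highly expressed reporter transcript |
| reads/triple | zt-NB, mean 24, shape 2 | positioned so ~15–20% of triples fall under the 10-read threshold — the filters do meaningful work at defaults |

Clone composition is *hallmark-guaranteed*: a clone of size 1 is its
category's hallmark cell (a neuron for a neuron-linked clone, etc.);
larger clones contain one founder-subtype cell, one hallmark cell, and
category-mixture draws for the rest. This makes the clone-level category
identifiable from clone contents, so exclusive classification can recover
the generative profile; the cost is a small, quantifiable eligibility bias
(size-1 clones of non-self-renewing categories contain no progenitor cell
and drop out of "clones containing the subtype" denominators, ~1 point at
default sizes). The category mixtures encode the emulated lineage
structure: Olig2-lineage clones are restricted (no neurons), S100a11
clones share with neurons, self-renewing clones are progenitors only.

Sequencing errors in barcodes are off by default (no error-correction step
exists downstream to exercise); barcode strings are random 40-mers (≥ 37
so the length filter is exercisable). `simulate_null()` is identical
except each cell's type is redrawn i.i.d. from the pooled frequencies,
destroying all clone–type association — the calibration target for the
coupling statistics.

**What the generator does not emulate:** ambient RNA, doublets, PCR
chimeras between barcodes, cell-type-dependent capture efficiency,
batch/animal effects, or realistic transcriptome structure beyond
NB counts with marker elevation. Passing recovery tests on this generator
therefore shows the *statistics* are implemented and calibrated correctly,
not that real data meet their assumptions.

# Calibration design for the null test

The type-I calibration of the coupling z-scores (null simulator, 10,000
permutations, |Z| > 1.96 rate ≈ 5%) is run on a generator configured with
an **even fate profile** (0.25 per category for both subtypes) at 500
clones. With the biased default profile the S100a11 state holds only
~1–2% of cells, its pairwise shared-counts live on {0, 1, 2}, and the
moment-based z-score for such pairs is visibly skewed — a two-sided 1.96
threshold then measures count discreteness, not calibration. The even
profile keeps every pairwise null count large enough for the normal
approximation to be the thing under test. The mean and variance of the
null z-distribution are checked on the same runs.

# Problem sizes in the test suite

The suite validates at sizes chosen to make sampling error small relative
to the tolerances while keeping a laptop-scale run: 500 clones (5 seeds)
for clone recovery (ARI ≥ 0.95), 500 clones × 10 seeds × 10,000
permutations for null calibration, 1,000 progenitor clones for fate
composition (± 0.05), 200 random ≤ 8-cell instances for the clustering
oracle, full enumeration of 7! label permutations for permutation
exactness, and 200 cells per group for the PCA-distance calibration.

# Known limitations

* Clone calling has no probabilistic model: a barcode collision between
  animals or a heavily truncated barcode set can merge or split clones
  silently. Inspect `clone_dendrogram()` around the cut, and call clones
  per reaction.
* The coupling null conditions on observed clone sizes and label margins
  only; if states differ systematically in capture rate, "chance" is
  defined relative to the captured data, not the tissue.
* z-scores for rare states are discrete and skewed (see the calibration
  section); treat |Z| thresholds for such pairs with caution, or increase
  `min_cells`/pool states.
* The PCA-distance normalizer uses random half-splits of the *whole*
  dataset; if the dataset is dominated by one subtype, D_s largely
  reflects that subtype's dispersion.
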