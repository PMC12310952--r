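# clonetrace

Clone calling and lineage-coupling analysis for lineage-barcoded
single-cell RNA-seq data.

## What this is for

Transposon-delivered lineage barcodes are inherited by all progeny of a
tagged progenitor and read out in the transcriptome of a droplet scRNA-seq
experiment. Given that evidence, `clonetrace` answers three questions a
clonal fate-mapping study asks:

1. **Which cells are clonal relatives?** Molecule-level barcode
   observations (cell–UMI–barcode triples) are filtered by read and UMI
   support (defaults: ≥ 10 reads per triple, ≥ 6 UMIs per cell–barcode
   pair, barcodes ≥ 37 bp), assembled into a sparse binary cell × barcode
   matrix, and clustered with **average linkage on Jaccard distance**
   between integration-barcode sets; cutting the dendrogram (default
   height 0.5) yields CloneIDs.
2. **Which cell states are lineage-coupled?** A clone is *shared* between
   two states if it has ≥ 2 cells of each. Observed shared-clone counts
   O are standardized against a permutation null (cell-state labels
   shuffled over cells, 10,000 permutations) as

   Z = (O − μ) / σ,

   positive for coupled, negative for anti-coupled states; Pearson
   correlations between z-rows give the clustered coupling heatmap.
3. **What are clones made of, and how stable is a population?**
   Restricted-vs-mixed clone fractions, UpSet-style intersection counts,
   exclusive fate classification with precedence rules, depth
   log-normalization (ln(1 + 10⁴·x/total)), a scrambled-normalized
   PCA-distance drift statistic (first 30 PCs; distance divided by the
   same quantity on random half-splits), and binned-control gene-set
   module scores.

A synthetic-data generator (`simulate_experiment()` / `simulate_null()`)
emulates a dual-progenitor cortical experiment — two radial-glia subtypes
with strongly biased fate output over neurons and two astrocyte lineages,
clones averaging 4.5 cells, a 10⁵-variant barcode library, multiple
integrations per founder, 75% barcode recovery — with complete ground
truth, so the entire pipeline is testable without any external data.

## Worked example

```r
library(clonetrace)

cfg    <- sim_config(n_progenitors = c(RGC_1 = 100, RGC_2 = 100), seed = 1)
sim    <- simulate_experiment(cfg)
pairs  <- filter_triples(sim$triples, min_reads = 10, min_umis = 6)
m      <- build_matrix(pairs, all_cells = sim$annotations$cell_id)
clones <- call_clones(m, cut_height = 0.5, annotations = sim$annotations)
st     <- clone_size_stats(clones)
sprintf("%d clones over %d cells, mean size %.2f", st$n_clones, st$n_cells, st$mean_size)
#> "197 clones over 638 cells, mean size 3.24"

coupling_zscores(clones, state_col = "subtype", n_perm = 10000, seed = 1)
#> <coupling_result: 5 states, 197 clones, 638 cells, 10000 permutations (seed 1)>
#> z-scores:
#>               Astro_Olig2 Astro_S100a11 Neuron RGC_1 RGC_2
#> Astro_Olig2          4.86         -0.09  -2.04  0.35  2.97
#> Astro_S100a11       -0.09          9.54  -0.22 -0.15 -0.24
#> Neuron              -2.04         -0.22   0.04  2.28 -3.72
#> RGC_1                0.35         -0.15   2.28  1.94 -3.34
#> RGC_2                2.97         -0.24  -3.72 -3.34 -1.44
```

Reading the z-matrix: `RGC_2` couples with Olig2-lineage astrocytes
(Z = 2.97) and is anti-coupled with neurons and with `RGC_1`
(Z ≈ −3.5), while `RGC_1` couples with neurons — the generator's built-in
lineage split, recovered from noisy barcode data. The strong diagonal for
`Astro_S100a11` is self-coupling (its few clones are internally
expanded). Fate composition of the recovered `RGC_2` clones:

```r
exclusive_fate_fractions(clones, "RGC_2")
#>        category  n  fraction
#> 1   olig2_astro 33 0.3626374
#> 2 s100a11_astro  0 0.0000000
#> 3        neuron 16 0.1758242
#> 4    self_renew 42 0.4615385
```

Note the visible effect of 75% barcode recovery: clones that lose their
differentiated cells to dropout are classified as progenitor-only, so
self-renewal is overcounted relative to the generative 50/34/16/0 split —
run the same call on `sim$truth` tables to see the unbiased fractions.
The whole chain also runs as one command with a reproducibility manifest:

```sh
Rscript scripts/pipeline.R --outdir out --seed 1
```

## Documentation

Every exported function carries roxygen documentation, and the methods
vignette (`vignettes/clonal-lineage-analysis.Rmd`) describes the models,
the default parameters and why they were chosen, what the simulator does
and does not emulate, and the package's numerical conventions
(deterministic tie-breaking in clone calling, permutation seeding,
degenerate-case handling).
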