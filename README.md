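# visgrad

Transcriptomic gradient analysis of human visual cortex.

## The problem

Human occipitotemporal cortex is tiled by 13 cytoarchitectonically
defined visual areas (cROIs), from striate cortex (hOc1) through the
extrastriate hOc areas to the fusiform regions FG1–FG4. Bulk microarray
data sampled across these areas (Allen-Human-Brain-Atlas-style triplets
of probe annotations, sample annotations with MNI coordinates, and
probe × sample expression) make it possible to ask how the transcriptome
changes along this processing hierarchy. `visgrad` is for researchers who
want to run — or stress-test on simulated data — the full analysis chain
behind that question:

1. **Preprocess**: drop probes lacking a gene symbol or Entrez ID,
   average probes per gene, z-score per gene within each donor, assign
   samples to cROIs by Euclidean distance in MNI space.
2. **Select**: per-gene one-way ANOVA across four cROI neighbourhoods
   ({hOc1}, {hOc2, hOc3}, {hOc4}, {FG}; hOc5 excluded for having only 2
   samples), keep the top ~1% (200 genes). A PCA-based selection is
   provided as a cross-check.
3. **Gradients**: WPGMA clustering splits the 200 genes into an
   *ascending* set (expression rising from hOc1 to FG4) and a
   *descending* set. The partition is tested against a linear hypothesis
   matrix `H` (one signed z-scored ramp per gene) by correlating the
   flattened matrices, with a null built from `n_boot` permutations of
   the ROI axis:
   `r = cor(vec(E), vec(H))`, `p = #{r_null >= r} / n_boot`.
4. **Hierarchy**: a rooted-leaf WPGMA dendrogram of the cROIs, anchored
   at hOc1 (at every merge the subtree closest to hOc1 goes left), an
   ordering bootstrap, and a leave-one-out winner-take-all classifier
   that predicts each sample's cROI from the correlation of its 200-gene
   vector with per-ROI fingerprints, scored in hierarchical steps.
5. **Anatomy**: correlations of the gradient profiles with cortical
   thickness and the T1w/T2w myelin proxy, a metric × cROI two-way
   ANOVA, nested distance-vs-hierarchy regressions, and a hypergeometric
   overlap test against marker-gene sets, reporting
   `z = (k − nK/N) / sd` standard deviations above chance.
6. **Development & species**: late-minus-early expression slopes per
   developmental stage with a gradient × stage interaction ANOVA and the
   crossover stage; macaque homolog slopes with pooled-variance t-tests.

A first-class synthetic-data module generates every input the pipeline
consumes — expression triplet, cROI atlas, anatomy, developmental series,
macaque data — with planted ground truth, so every stage is validated by
recovery.

## Worked example

```r
library(visgrad)

cfg   <- synth_config(seed = 1)          # reference conditions
atlas <- generate_atlas(cfg)
sim   <- generate_expression_dataset(cfg, atlas)

expr <- filter_and_collapse_probes(sim$expression, sim$probes)
zmat <- zscore_by_donor(expr, sim$samples$donor_id)
asg  <- assign_samples_to_crois(sim$samples, atlas)
grp  <- group_crois(asg); grp$group[grp$excluded] <- NA

sel <- anova_rank_genes(zmat, grp)
top <- select_top(sel, 200)
cm  <- croi_mean_matrix(zmat, asg, gene_subset = top, atlas = atlas)

(part <- cluster_genes(cm))
#> Gradient partition: 140 ascending, 60 descending genes (top-merge ratio 2.02)

H <- build_hypothesis_matrix(part, 13)
gradient_correlation_test(part$zmatrix, H, n_boot = 1000, seed = 2)
#> Gradient test (full): r = 0.912, p < 0.001 (n_boot = 1000)

(hier <- rooted_leaf_dendrogram(cm, anchor = "hOc1"))
#> Rooted-leaf cROI hierarchy (anchor hOc1):
#>   hOc1 -> hOc2 -> hOc3v -> hOc3d -> hOc4v -> hOc4d -> hOc4lp -> hOc4la -> hOc5 -> FG1 -> FG2 -> FG3 -> FG4

loo_classify(zmat[top, ], asg, hier, n_boot_null = 200, seed = 3)
#> LOO winner-take-all classifier: 331 samples, median step error 0
#>   shuffled-gene null: median of medians 4 (n = 200)

hypergeometric_overlap(paste0("g", 1:200),
                       paste0("g", c(1:43, 300:1086)), 20737)
#> Hypergeometric overlap: k = 43 of n = 200 (21.5%), expected 8.01
#>   z = 12.7 sd above chance, p = 7.89e-20
```

Reading the output: the 200 most differentially expressed genes split
140/60 into opposed gradients, and the final merge of the gene dendrogram
stands about twice as tall as the one below it — a genuinely binary
structure. The observed expression matrix correlates at r = 0.912 with
the idealized ramp matrix, and no ROI-shuffled null iteration reaches it.
The cROI dendrogram orders the 13 areas exactly along the planted
posterior-to-anterior hierarchy, and held-out samples are located to
their region of origin with a median error of 0 hierarchical steps
(shuffling gene labels degrades this to 4, the chance level for 13
leaves). The hypergeometric report shows a 43-gene overlap where 8
would be expected by chance, 12.7 standard deviations above it.

## Vignette

`vignettes/visual-cortex-gradients.Rmd` documents the statistical model,
the synthetic-data generator and the reasoning behind its default
conditions, the numerical conventions (tie-breaks, degenerate cases,
permutation-p reporting), and the known limitations of what synthetic
recovery can demonstrate.
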