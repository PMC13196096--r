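# caae — class-aware adversarial autoencoder integration of multi-dataset transcriptomes

`caae` integrates bulk gene-expression datasets collected on heterogeneous
platforms into a single corrected expression space. It is aimed at anyone
assembling a multi-dataset compendium — many small public datasets, mixed
microarray and RNA-seq platforms, partially overlapping disease classes —
where sample similarity is dominated by dataset of origin rather than
biology, and where classes of interest often never co-occur in the same
dataset.

## What it computes

**Hierarchical cross-dataset logFC.** Every class pair is classified from
the dataset–class incidence table as *directly shared* (co-occur in a
dataset), *indirectly shared* (linked through a bridge class) or
*non-overlapping*. Direct pairs are estimated by within-dataset contrasts
with a concordance filter (profiles kept when their best Pearson
correlation with another profile is ≥ 0.3, applied above 3 datasets);
indirect pairs bridge two datasets through the median profile of the
shared class (dataset pairs matched by bridge-profile similarity: top 3
per candidate, preferring similarity > 0.6, else the global top 10) before
a joint least-squares batch adjustment; non-overlapping pairs merge and
adjust, flagged low-confidence. The result is a class × gene logFC matrix
against a baseline class, with sign convention logFC(a, b) = x̄ₐ − x̄_b.

**Baseline-center refinement.** The baseline profile is refined by gradient
descent (100 iterations, learning rate 0.001, L2 anchor weight scheduled
linearly from 1e-4 to 1e-3) so that one-hop class profiles predicted from
different baselines, center_b + logFC(c, b), agree.

**The model.** An MLP encoder (512-256-128-64, CELU, dropout) maps samples
to latent components Z; all bias-free decoder layers collapse into a
gene-level signal matrix W; a fixed class-specific proportion tensor P
(per-gene softmax over class templates) modulates the reconstruction

    X̂[i, g] = Σ_d Z[i, d] · P[d, c_i, g] · C · W[d, g]

Training minimizes reconstruction + signal anchoring ‖W − W_expected‖² +
latent class centering + component consistency + a cooperative class
discriminator, while an adversarial batch discriminator reaches the
encoder through gradient-sign reversal (Adam, lr 1e-4, batch 128). The
corrected matrix is the eval-mode reconstruction.

**Evaluation.** Centroid silhouettes (inter-class term = mean distance to
the 10 nearest other-class centroids), a chi-square k-NN batch-mixing
rejection rate, top-100 differential-gene overlap, Spearman ratio
consistency, universal high-frequency gene rankings and class-specificity
scores.

**Synthetic compendia.** `generateCompendium()` draws class templates,
gene-wise location–scale batch effects and noise under a designed
co-occurrence graph, with exact ground truth for every quantity above.

## Worked example

```r
library(caae)

cfg <- simulationConfig(n_datasets = 4, mode = "chain-indirect",
                        n_classes = 3, samples_per_class = 15,
                        n_genes = 300, seed = 42)
sim  <- generateCompendium(cfg)
comp <- preprocessCompendium(sim$datasets)
comp
#> ExpressionCompendium: 300 genes x 120 samples
#>   datasets: 4 (DS1, DS2, DS3, DS4)
#>   classes: disease1, disease2, healthy
#>   provenance steps: 9

relmap <- classifyPairRelationships(comp)
relmap
#> PairRelationshipMap: 3 pairs (2 direct, 1 indirect, 0 isolated)

recs <- computeLogFC(comp, relmap = relmap)
lfc  <- assembleLogFCMatrix(recs, "healthy")
cor(logfcValues(lfc)["disease2", ], sim$truth$logfc["disease2", ])
#> [1] 0.953   # indirect pair, recovered through the disease1 bridge

ctr <- initCenters(comp, "healthy")
fit <- fitCAAE(comp, lfc, ctr, modelConfig(epochs = 60, seed = 0),
               batch_by = "dataset")
evaluateIntegration(correctedMatrix(fit), assayMatrix(comp),
                    classLabels(comp), datasetIds(comp))
#> EvaluationReport
#>   class silhouette (mean): corrected 0.011 | raw 0.017
#>   batch silhouette (mean): corrected -0.140 | raw 0.514
#>   batch-mixing rejection:  corrected 0.442 | raw 1.000
```

Reading the report: the *batch* silhouette collapses from 0.514 to −0.140
(samples no longer cluster by dataset) and the batch-mixing rejection rate
falls from 1.0 to 0.44 (neighborhoods mix across datasets), while the
*class* silhouette is held at the level of the raw data — batch structure
is removed, class structure retained. The indirect-pair logFC, estimated
without any dataset containing both classes, correlates with the planted
truth at r = 0.95.

A command-line wrapper over the same functions is in
`inst/scripts/caae-cli.R` (subcommands `simulate`, `preprocess`, `fc`,
`train`, `evaluate`).

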