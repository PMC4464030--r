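# mgrnet — miRNA–gene regulatory networks from combined target predictions

miRNA-target prediction algorithms disagree with each other and drown their
few true positives in noise, while experimental validation provides only
positive labels — an unvalidated pair is unknown, not false. `mgrnet`
implements the computational pipeline for this setting:

1. **Positive-unlabeled (PU) score combination.** A bagged ensemble of
   probabilistic classifiers fuses the score vectors of several upstream
   prediction algorithms into one reliability score per miRNA–gene pair.
   Under the selected-completely-at-random assumption (validated pairs are a
   random sample of the true interactions with constant label frequency
   *c*), the labeled-vs-unlabeled classifier output *g(x)* is converted into
   Elkan–Noto case weights, w(x) = ((1−c)/c)·g(x)/(1−g(x)), and a weighted
   refit yields calibrated interaction probabilities. *c* itself is
   estimated as the mean *g* over held-out positives.
2. **Hierarchical overlapping biclustering.** From the weighted bipartite
   adjacency matrix *A*, bicliques on the β-thresholded graph are greedily
   aggregated maximizing jaccard(C′r, C″r) · q(aggregate, A), where the
   compactness q(C, A) = (|Cr||Cc|)⁻¹ Σ Σ A(x, y) is the mean block score.
   Overlaps between biclusters are detected with per-dimension linear SVM
   separating hyperplanes (misclassified objects are shared), and close
   bicluster pairs (centroid distance within 2σ′ + 2σ″ on either dimension)
   are merged when the union's compactness exceeds α — iterated level by
   level into a hierarchy of miRNA–gene modules.
3. **Functional ranking.** Modules are ranked by Gene Ontology coherence:
   SimGIC gene similarity (IC-weighted Jaccard of ancestor-closed term
   sets, IC(t) = −log p(t)) and a one-tailed Welch t-test of intra- vs
   inter-module similarity, giving per-module p_BP and p_MF.

Seeded generators (planted-bicluster matrices, SCAR-labeled PU score sets,
toy ontologies) make the whole pipeline testable offline; OBO/GAF/TSV
readers and writers, JSON hierarchy exports and GraphML network exports
connect it to real data.

The package is written for computational biologists working on miRNA
regulation who need reliability-ranked interactions and interpretable
co-targeting modules rather than raw prediction dumps.

## Worked example

Plant four overlapping miRNA–gene modules, extract and rank them:

```r
library(mgrnet)

design <- plantedDesign(40, 160, overlap_fraction = 0.2, seed = 7)
sim <- plantedMatrix(design)
sim$matrix
#> InteractionMatrix: 40 miRNAs x 160 genes, 5292 scored pairs
#>   score range [0.050, 1.000]

step1 <- extractBicliques(sim$matrix, beta = 0.5)
length(step1$bicliques)
#> [1] 4

hier <- buildHierarchy(step1$bicliques, sim$matrix, alpha = 0.3, beta = 0.5)
hier
#> Hierarchy: 3 level(s), alpha = 0.30, beta = 0.50
#>   level 1: 4 bicluster(s)
#>   level 2: 2 bicluster(s)
#>   level 3: 1 bicluster(s)
```

The four planted modules are recovered exactly at level 1 (each level-1
bicluster is one planted module: 40 genes with its 10 planted plus 2
overlap-shared miRNAs); the 20% miRNA overlap between adjacent modules
drives the level-2 and level-3 merges.

The PU combiner on synthetic SCAR data with true label frequency 0.5:

```r
pu <- puScores(n = 10000, d = 2, prior = 0.5, label_frequency_c = 0.5,
               separation = 0.6, seed = 1)
pu
#> PUDataset: 10000 pairs x 2 algorithms, 2453 labeled positive

fit <- puCombine(pu, K = 10, seed = 1)
round(fit$c, 3)          # estimated label frequency (truth: 0.5)
#> [1] 0.501
round(evaluateAUROC(fit$scores, pu@truth), 3)
#> [1] 1
```

The estimated label frequency lands on the planted 0.5 and the final
reliability scores perfectly separate the hidden true interactions on this
separable fixture.

A ready-made command-line front end with `simulate` / `combine` /
`bicluster` / `rank` / `query` / `export` subcommands ships at
`inst/cli/mgrnet.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mgrnet.R", package = "mgrnet"))')
Rscript $CLI simulate --what matrix --seed 4 --out sim
Rscript $CLI bicluster --matrix sim/matrix.tsv --beta 0.5 --alpha 0.3 \
        --out hierarchy.json
```

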