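---
title: "Methods: combining miRNA-target predictions and extracting regulatory modules"
author: "mgrnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining miRNA-target predictions and extracting regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrnet)
```

# The problem

Computational miRNA-target prediction algorithms (TargetScan, PITA, picTar,
miRanda, ...) disagree with each other, return thousands of candidates per
miRNA, and carry many false positives. Experimental validation covers only a
tiny fraction of the candidate space, and genuinely negative examples are
essentially unavailable: an unvalidated pair is *unknown*, not false. mgrnet
addresses two linked tasks on this kind of data:

1. **Score combination.** Fuse the per-pair scores of several upstream
   prediction algorithms into a single reliability score in $[0, 1]$, using
   the validated pairs as *positive* labels and everything else as
   *unlabeled* — a positive-unlabeled (PU) learning problem.
2. **Module extraction.** From the resulting weighted bipartite graph
   (miRNAs $\times$ genes, adjacency matrix $A$), extract hierarchically
   organized, possibly overlapping biclusters — a miRNA module paired with
   the gene module it co-targets — and rank them by Gene Ontology functional
   coherence.

# The PU combiner

Each candidate pair is represented by its vector of upstream algorithm
scores (features), with a binary flag: validated (labeled positive) or
unlabeled. Using prediction *outputs* as features sidesteps the collinearity
of the algorithms' underlying sequence features, in the spirit of
meta-learning.

The combiner has three steps:

1. **Representation** — `puDataset()`. Missing scores are imputed with 0 by
   default: the absence of a prediction is treated as that algorithm voting
   "no interaction". The imputation value is configurable.
2. **Nontraditional classifier** — `fitNontraditional()`. A probabilistic
   classifier for *labeled vs unlabeled*, giving $g(x) \approx P(s = 1 \mid
   x)$.
3. **Weighted classifier** — `fitWeighted()`. Under the
   selected-completely-at-random (SCAR) assumption — positives are labeled
   with a constant probability $c$ independent of the features — the
   nontraditional output can be converted into weights: each unlabeled
   example enters once as a positive with weight
   $w(x) = \frac{1-c}{c}\,\frac{g(x)}{1-g(x)}$ and once as a negative with
   weight $1 - \min(w(x), 1)$; labeled examples are positives with weight 1.
   The refit model's positive-class probability is the final reliability
   score.

The label frequency $c$ is estimated by `estimateLabelFrequency()` as the
mean $g$ over a held-out fraction (default 0.2) of the labeled positives:
for a true positive in a region where $P(y = 1 \mid x) \approx 1$,
$g(x) \to c$. This mean-over-holdout estimator was chosen because it is the
simplest consistent estimator under SCAR; alternatives (max-based, isotonic)
are noisier at the sample sizes involved.

## Ensembling and the base-rate correction

Validated pairs are vastly outnumbered by unlabeled ones, so a single fit is
dominated by the unlabeled class. Both stages therefore bag $K$ members
(default $K = 10$): every member trains on *all* positive-role examples plus
`negatives_per_member` unlabeled/negative-role examples sampled with
replacement (default: as many as there are positives, i.e. balanced
members). An example is scored by averaging the members whose training
sample contained it; an example seen by no member falls back to the
all-member mean (the natural completion of the rule, which otherwise leaves
it undefined).

Balanced members see a much higher labeled base rate than the population,
which would bias $g$ upward — and with it the estimate of $c$. Member
probabilities are therefore mapped back to the population prior with the
standard case-control intercept correction: if a member sampled the negative
class at rate $r$, its corrected log-odds are the raw log-odds plus
$\log r$. With this correction the $c$ estimator is unbiased under the
balanced default; without it, it is not.

The base member is a logistic regression (via `stats::glm.fit` with a
quasibinomial link, so the fractional Elkan–Noto weights fit without
warnings). Any probabilistic classifier satisfies the contract; logistic is
the default because score features are low-dimensional, bounded and roughly
monotone in reliability. The weight cap (default $w \le 50$) guards against
$g(x) \to 1$ blowing up the positive weight of a single unlabeled example.

Baselines `baselineSA()` (plain mean of non-missing scores) and
`baselineWSA()` (reliability-weighted mean) reproduce the simple-averaging
combiners the PU approach is compared against, and
`evaluateCoverage()` / `evaluateAUPRC()` implement the evaluation protocol:
how many top-ranked interactions must be returned to cover a given
percentage of the validated targets, and the area under the precision-recall
curve with tied scores grouped at one operating point. For coverage, the
required count is a percentage of *all* validated targets of the miRNA; a
percentage is "not reachable" (`NA`) when the scored set simply does not
contain enough of them — mirroring how databases that miss validated targets
cannot cover them no matter how many rows they return.

# Hierarchical overlapping biclustering

## Step 1: bicliques

Interactions with score strictly greater than the reliability threshold
$\beta$ form the *reliable* graph. Degree statistics drive the aggregation
(for the miRNA-to-mRNA direction; the other direction is symmetric):

* `avg_opposite` — the average number of miRNAs targeting each mRNA;
* `min_own` — the outlier-proof minimum number of mRNAs targeted per miRNA,
  computed after discarding the lowest 0.15% of the per-miRNA counts
  (the 3-sigma rule under a Gaussian degree assumption; with small inputs
  $\lfloor 0.0015\,n\rfloor = 0$ and nothing is trimmed);
* `abs_min_own` — the untrimmed minimum.

Each miRNA seeds a biclique with all its reliable targets. Pairs are then
greedily aggregated: the aggregate of $C'$ and $C''$ keeps the *intersection*
of the gene sets and the *union* of the miRNA sets, it is admissible when it
retains at least `min_own` genes and at most `avg_opposite` miRNAs, and at
every step the admissible pair maximizing

$$\mathrm{jaccard}(C'_r, C''_r) \cdot q(\mathrm{aggregate}(C', C''), A)$$

is merged, where $q(C, A) = \frac{1}{|C_r||C_c|}\sum_{x \in C_r}\sum_{y \in
C_c} A(x, y)$ is the *compactness* (mean score over the bicluster block,
absent cells counting 0). Ties are broken by the lexicographically smallest
joined id, and ids record lineage by joining founders with `_` — so the
whole step is deterministic and invariant to input order. Aggregates remain
true bicliques on the thresholded graph because intersected genes interact
with every miRNA of both founders.

A note on the admissibility condition: the two printed constraints can be
read with the roles of intersection and union swapped. This implementation
requires $|C'_r \cap C''_r| \ge \texttt{min\_own}$ and $|C'_c \cup C''_c|
\le \texttt{avg\_opposite}$ — i.e. the constraints are evaluated on the
*aggregate*, consistent with both the aggregation definition and the design
goal that a good biclique should contain roughly `avg_opposite` miRNAs while
keeping as many genes as possible. Likewise, $q$ in the selection objective
is computed on the aggregate block.

Bicliques with fewer than `abs_min_mirna` miRNAs or `abs_min_mrna` mRNAs are
pruned (each absolute minimum comes from the direction whose seeds it
counts); objects covered by no surviving biclique are reported as
isolated/noise. Finally the two directions' outputs are merged, collapsing
exact duplicates only.

## Step 2: overlap detection and merging

Objects are embedded as their raw score profiles (a miRNA as its row of
$A$, a gene as its column). No other coordinate space is shared by both
object kinds, and profiles are exactly what the biclustering already
groups, so they are the natural geometry.

*Overlap detection*: for every bicluster pair at a level and each dimension,
a linear SVM (`e1071::svm`, unit cost — "separating hyperplane" implies a
linear max-margin boundary) is trained on the *exclusive* members of the two
biclusters and applied back to them; a misclassified object plausibly
belongs to both biclusters and is **added** to the one that did not contain
it. Members are never removed. Additions are collected across all pairs and
applied at the end of the pass (batch semantics), making the result
independent of pair ordering. A dimension with no exclusive member on one
side is skipped.

*Merging*: biclusters $C'$, $C''$ are merge candidates when
$\mathrm{dist}(C', C'') - 2\sigma(C') - 2\sigma(C'') \le 0$ on at least one
dimension, where dist is the Euclidean distance between member centroids and
$\sigma$ is the scalar RMS distance of members to their centroid (a scalar
radius, because the condition subtracts it from a scalar distance). A
candidate pair is merged — union on both dimensions — only if the union's
compactness strictly exceeds the user threshold $\alpha$; a bicluster
involved in several passing pairs takes only its maximum-$q$ merge (greedy,
best first, ties by joined id). Unmerged biclusters are copied to the next
level unchanged, so every level is a complete clustering and a "best level"
can be selected downstream by rank statistics.

`buildHierarchy()` iterates overlap-then-merge per level, recording level 1
as the step-1 output after the first overlap pass, and stops when a round
merges nothing or `max_levels` (default 10, comfortably above the 5–8 levels
typical of real score matrices) is reached. Lower $\alpha$ facilitates
merging and hence deeper hierarchies; the package asserts the resulting
monotonicity on planted fixtures.

## Step 3: functional ranking

Functional similarity between genes is SimGIC:

$$\mathrm{SimGIC}(x_1, x_2) = \frac{\sum_{t \in GO(x_1) \cap GO(x_2)} IC(t)}
{\sum_{t \in GO(x_1) \cup GO(x_2)} IC(t)},$$

with $IC(t) = -\log p(t)$ and $p(t)$ the fraction of annotated genes whose
term set contains $t$. Natural logarithm by default (the base is
configurable; it does not cancel out of SimGIC in general, but any fixed
base gives the same *ranking* structure for identical term-set geometries).
$GO(x)$ is the ancestor-closed term set by default — the conventional choice
for SimGIC — with a flag to use direct annotations only. `is_a` and
`part_of` are both treated as subsumption; other relations are ignored.
Unannotated genes yield an *undefined* similarity that is excluded from
samples rather than scored 0, so sparsely annotated modules are not
penalized; `n_annotated` is reported so users can judge support.

For each bicluster $C$ at level $L$, the intra sample collects SimGIC over
gene pairs within $C$ and the inter sample over pairs from $C$ to genes of
other biclusters at $L$. A one-tailed two-sample t-test of
$H_0: \mu_0(C) = \mu(L, C)$ vs $H_1: \mu_0(C) > \mu(L, C)$ gives the
p-value; the lower the p-value, the more coherent the bicluster. Welch's
unequal-variance variant is used because the two samples have very
different sizes and spreads; each sample is uniformly subsampled (seeded) to
at most `cap = 2000` pairs to keep large biclusters tractable. Degenerate
cases (fewer than two values in either sample; both samples constant and
equal) give $p = 1$. Rankings are computed per namespace (BP and MF) and
reported as `p_bp` and `p_mf`, with the significance threshold for summary
counts fixed at 0.05 and no multiple-testing correction, matching how such
bicluster reports are conventionally summarized.

# Synthetic generators and what they do (not) show

All generators are pure functions of their seed.

* `plantedMatrix()` — block-structured score matrices: in-module cells
  $U(0.7, 1.0)$, background $U(0, 0.2)$ sparsified below 0.05 (keeping the
  matrix sparse like real prediction data), optional overlap planting a
  fraction of each module's miRNAs into the next module. The default layout
  (4 disjoint modules of 10 miRNAs $\times$ 40 genes) is the package's
  reference recovery benchmark: step 1 plus the hierarchy must recover each
  module at level 1 with member-set Jaccard $\ge 0.9$.
* `puScores()` — SCAR-labeled PU data with per-dimension uniform
  class-conditionals shifted by `separation` (the simplest shape satisfying
  the method's assumptions): positives $U(s, 1)$, negatives $U(0, 1-s)$ per
  dimension. At $s \ge 0.5$ the supports are disjoint and the true posterior
  is 0/1, which makes parameter recovery checkable exactly; at $s = 0$ any
  classifier is at chance. The reference conditions ($n = 10{,}000$, $d=2$,
  prior 0.5, $c = 0.5$, $s = 0.6$) recover $\hat c$ within $\pm 0.05$.
* `toyOntology()` — random tree ontologies of controlled depth with
  dedicated high-IC leaf terms shared by planted coherent gene groups, plus
  uniform random annotation noise (3 direct terms per gene by default).

These fixtures demonstrate *algorithmic correctness* — recovery of planted
structure, parameter recovery, calibration under the null — not biological
performance. Real prediction scores are not uniform, real validated labels
are not exactly SCAR (validation effort follows popularity), and real GO
annotation is far sparser and deeper than the toy trees. Passing tests on
these fixtures therefore show the machinery is faithful, not that any
particular biological dataset will yield coherent modules.

# Numerical choices and edge cases

* Score threshold comparisons are strict (`> beta`) everywhere, matching
  the definition of a "reliable" interaction; the score *filter*
  (`filterByScore()`) is inclusive (`>= threshold`) as a query convenience.
* All object indices are kept lexicographically sorted and every tie is
  broken by id, so the full pipeline is deterministic given the seeds.
* The trim count for `min_own` is $\lfloor 0.0015\, n\rfloor$; small inputs
  are untouched.
* An empty reliable graph (no score above $\beta$), an empty bicluster
  dimension, a single-class truth vector, and a zero-size holdout are hard
  errors rather than silent degeneracies.
* Problem sizes in the tests and the acceptance script (planted 40 x 160
  matrices, $n = 10^4$ PU samples, 200 null biclusters over 300 genes,
  10 seeds per property) were chosen as the smallest sizes at which the
  law-of-large-numbers margins in the checks are comfortable.

# Known limitations

* Greedy aggregation and greedy best-$q$ merging are order-deterministic
  but not globally optimal; no beam search or alternative merge orders are
  attempted.
* The SVM overlap step assumes linear separability of non-overlapping
  biclusters in score-profile space; heavily corrupted profiles can add
  spurious shared members (they are never removed, so errors only enlarge
  biclusters).
* Inter/intra similarity samples share genes, so the t-test's independence
  assumption is approximate; the null calibration test bounds the practical
  effect (the fraction of $p < 0.05$ stays within $[0.01, 0.10]$ under
  exchangeable annotations at the reference sizes).
* ID mapping (symbol aliases, Entrez) and evidence-code filtering are out
  of scope: gene identity is the case-sensitive official symbol after GAF
  uppercasing.
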