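---
title: "Qualitative gene-pair signatures from relative expression orderings"
author: "reopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative gene-pair signatures from relative expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The model

Let $x_{g,s}$ be the measured expression of gene $g$ in sample $s$, on any
scale. For a gene pair $(i, j)$ the *relative expression ordering* (REO) in
sample $s$ is the sign of $x_{i,s} - x_{j,s}$. Because the ordering depends
only on the within-sample ranking, it is invariant under any strictly
increasing transform applied to that sample — log transforms, positive
affine rescaling, quantile shifts, rank replacement. This is the property
that makes REO-based signatures portable across microarray and RNA-seq
platforms, robust to batch effects and normalization choices, and applicable
to a *single* sample with no reference cohort.

The discovery procedure, given a case cohort and a control cohort:

1. **Stable pairs.** A directed pair $(i, j)$ is *stable* in a class when
   $x_i > x_j$ strictly in at least a fraction $\theta$ of that class's
   samples. We use $\theta = 0.85$, with an inclusive comparison
   ($\geq$). Exact ties count toward neither orientation; since
   $\theta > 1/2$, at most one orientation of a pair can be stable.
2. **Reversal pairs.** A pair stable as $i > j$ in cases and as $j > i$ in
   controls is a *reversal pair* — the unit feature of the signature. We
   store it in the case orientation (gene $i$ is the gene higher in cases).
3. **Whitelist filtering.** Optionally, keep only pairs whose *both* genes
   belong to a user-supplied gene set. The motivating use case is a list of
   secreted-protein genes, so that a tissue-derived signature remains
   measurable in blood.
4. **Ternary encoding.** Each sample becomes a vector over the reversal
   pairs: code $0$ when $x_i > x_j$ (the case pattern), $1$ when
   $x_i < x_j$, and $-1$ for every other situation — an exact tie, or a
   gene not measured on the platform. Encoding is strictly per sample.

## Feature ranking

Reversal-pair features are ranked on their ternary codes, treated as three
categorical levels.

**mRMR.** Relevance and redundancy are both measured by plug-in discrete
mutual information in nats,
$MI(f, t) = \sum p(f,t)\,\ln\frac{p(f,t)}{p(f)\,p(t)}$ with $0 \ln 0 = 0$.
The printed criterion is set-level (mean relevance of the selected set
minus mean pairwise redundancy), which does not by itself prescribe a
search scheme; we use the canonical greedy incremental *difference form* —
first pick $\arg\max_f MI(f, T)$, then repeatedly pick
$\arg\max_f \left[ MI(f,T) - \tfrac{1}{|S|}\sum_{s \in S} MI(f, f_s)\right]$
— and verify it against exhaustive subset search on small constructed
instances in the test suite. Exhaustive search over hundreds of candidate
pairs is infeasible, and greedy mRMR is standard practice.

**MRMD.** Each feature scores
$|r(f_i, T)| + \bar d_i$, where $r$ is the Pearson correlation with the
class coded 0/1 and $\bar d_i$ is the mean cosine distance
$1 - \cos(f_i, f_j)$ to every other candidate. We take the absolute
correlation because both reversal directions are informative, and weight
the two terms equally (the underlying method family admits weight variants;
nothing in our use case motivates a non-unit weight, and the weights are
not exposed as tuning knobs). Features are ranked once by descending score.

Ties anywhere break lexicographically by pair id (`genei|genej`), so both
rankers are deterministic and invariant to the input order of features.

**Degenerate inputs.** The exported `cosineDistance()` refuses zero
vectors, for which the quantity is undefined. Inside `mrmdRank()` a
zero-norm feature (a pair coded 0 everywhere, say) is assigned distance 1 —
the neutral value, equidistant in the orthogonal sense — so one
uninformative feature cannot abort a ranking; its relevance is 0 and it
sinks to the bottom regardless. Zero-variance features trigger a warning
and relevance 0 in `pearsonRelevance()`.

## Classifiers and incremental feature selection

`classifierSpec()` exposes eight classifier kinds. Settings stated for the
published pipeline are the defaults: RBF-kernel SVM with $\gamma = 2$ (cost
1, unstated, left at the library default), XGBoost with 25 rounds and a
binary-logistic objective, AdaBoost.M1 over decision stumps (single-split
trees), k-nearest neighbours with $k = 1$ (the IBk default of the Weka
toolchain the original work used; exposed as a parameter). Two kinds are
explicit approximations and are documented as such: `decision_tree` is a
CART tree via rpart standing in for Weka's J48/C4.5, and `lmt` is plain
logistic regression standing in for Weka's logistic model trees. No claim
of equivalence with the Weka internals is made for those two. AdaBoost.M1
with stumps is implemented in-package because no boosting library is
among the package's dependencies; it is the textbook algorithm
($\alpha_m = \tfrac12\ln\frac{1-e_m}{e_m}$ over exhaustively enumerated
ternary-threshold stumps) and is exercised by the same contract tests as
every other kind. Naive Bayes uses Laplace smoothing of 1 so that a code
level unseen in training does not zero out a posterior.

All fits run under an explicit seed (default 20240304) with the session RNG
restored afterwards; identical input plus identical seed gives identical
predictions. Prediction scores are oriented so that higher means case
(needed for ROC analysis); for margin-based scores the orientation is
determined on the training data.

**IFS.** Given a ranked list, incremental feature selection fits the
classifier on the top-$k$ features for $k = 1 \ldots K$, records the
evaluation metric, and selects the smallest $k$ attaining the maximum. The
default evaluation protocol is resubstitution on the training set. Whether
the original IFS accuracies were resubstitution or cross-validated is not
stated in the source work; uniformly perfect training-set values suggest
resubstitution, so that is the default here, while `cv = k` switches to
stratified k-fold cross-validation (deterministic seeded folds) as the
statistically safer protocol. The IFS curve should be read as a selection
device, not a performance estimate: resubstitution accuracy is optimistic
by construction.

## Metrics

With cases as positives: $Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$,
$Acc = (TP+TN)/n$, $F1 = 2TP/(2TP+FP+FN)$. A metric whose denominator is
zero raises an error rather than returning NaN — a case-only validation
cohort supports sensitivity but not specificity, and the caller must say
which metrics it wants. AUC is the area under the empirical ROC (FPR on
the x-axis), computed through the rank-based Mann–Whitney identity with
half credit for ties, and tested against a brute-force pairwise count. The
95% CI uses DeLong's analytic method by default because it is
deterministic; a seeded stratified bootstrap is available. Both are
delegated to pROC and truncated to $[0,1]$.

## The synthetic cohort generator

`simulateCohorts()` emulates the data layout every pipeline stage needs:
two labelled cohorts, a background of unordered genes, and a set of planted
reversal pairs with controlled stability.

* Background genes are iid log-normal (meanlog 5, sdlog 1) per sample. The
  marginals are arbitrary by design: REO logic sees only within-sample
  orderings, and the invariance tests enforce exactly that.
* Each planted pair shares a per-sample log-normal base level; the two
  genes sit at $\pm\,\delta/2$ around it on the log scale with
  $\delta = |N(0.2, 0.05)| + 10^{-6} > 0$, and *which* gene takes the high
  side is a per-sample Bernoulli draw — probability `stabilityCase` for the
  case pattern in case samples, `stabilityControl` for the reversed pattern
  in controls. Ordering control is therefore exact (the realized
  concordance is a binomial fraction with the stated mean), and orderings
  are strict almost surely.
* The offset is deliberately *small* against the between-gene sdlog of 1.
  A large offset would make the high-side gene of one pair order
  systematically above the low-side gene of *other* pairs, turning
  cross-pair combinations into spurious reversal signals; at
  $\delta \approx 0.2$ cross-pair orderings stay near chance (~0.56
  concordance) and the planted pairs are the only systematic reversal
  signal. This matters for the recovery tests, which demand exact
  planted-set recovery with zero background false positives.
* All randomness flows from one seed; the same seed reproduces the cohort
  bit-identically.

What the generator does **not** emulate: realistic microarray noise or
probe effects, batch structure, correlated co-expression modules, RNA
degradation, or class-dependent library composition. Passing tests on
these cohorts demonstrate the pipeline's correctness contracts (recovery,
invariance, determinism), not clinical performance on real tissue.

## Problem sizes and runtime choices

The package's own test suite and acceptance script run at a deliberate
desk scale chosen to finish in seconds while keeping every property
non-trivial: discovery cohorts of 100 case / 50 control samples over 11
planted pairs and 200 background genes (222 genes, ~24.5k unordered pairs);
oracle-equivalence checks on 50 random matrices of at most 8 genes by 12
samples, where exhaustive enumeration is feasible; 20-seed batteries for
the stochastic recovery properties. Stable-pair mining is the only
quadratic stage, O(G²·n); at these sizes a mining pass takes well under a
second. For genome-scale inputs (~20k genes) the same code path applies
but the pair matrix has ~2×10⁸ entries per class — tractable in memory but
minutes-scale; the `geneSubset` argument of `mineStablePairs()` allows
pre-restriction (e.g. to a whitelist) at the cost of deviating from the
default order of operations, which filters *after* reversal detection.

## Known limitations

* Mining across multiple platforms simultaneously, meta-analytic pooling
  of cohorts, and unmeasured-gene reconciliation before mining are out of
  scope; genes absent from a platform surface only at encoding time, as
  code $-1$.
* The 11-pair packaged signature ships as pairs only. No fitted SVM
  weights are published for it, so classification with it requires
  training on user-supplied or synthetic cohorts; the resulting decision
  boundary is the user's, not the published one.
* The tie rule (exact equality counts toward neither orientation during
  mining, and encodes as $-1$) is this package's documented choice; the
  source work defines only strict orderings and does not state how ties
  were handled at genome scale.
* `decision_tree` and `lmt` approximate, not reproduce, the Weka J48 and
  LMT classifiers.

## A worked run

```{r example, eval = FALSE}
sim <- simulateCohorts(nBackgroundGenes = 200, nPlantedPairs = 11,
                       nCase = 100, nControl = 50,
                       stabilityCase = 1, stabilityControl = 1,
                       seed = 20240304)
labs <- sim$labels
stableCase <- mineStablePairs(sim$matrix, names(labs)[labs == "case"],
                              threshold = 0.85, classLabel = "case")
stableControl <- mineStablePairs(sim$matrix, names(labs)[labs == "control"],
                                 threshold = 0.85, classLabel = "control")
rev <- findReversalPairs(stableCase, stableControl)
enc <- encodeProfiles(sim$matrix, rev)
rk <- mrmrRank(enc, labs)
ifs <- incrementalFeatureSelection(rk, enc, labs, classifierSpec("svm_rbf"))
ifs
```

`runPipeline()` wraps the same stages behind a config list or YAML file and
writes every artifact (pair sets, encoding, ranking, IFS curve, model,
metrics) under an output directory stamped with a config hash.
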