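# reopair

Qualitative gene-pair signatures from within-sample relative expression
orderings (REOs), for two-class transcriptome diagnosis.

## The problem and who this is for

Quantitative expression signatures travel badly: microarray and RNA-seq
intensities live on different scales, normalization choices shift them, and
batch effects and RNA degradation distort them. The *ordering* of two genes
within one sample — is gene *i* expressed above gene *j*? — survives all of
that, because it is invariant under any strictly increasing transform of
that sample's measurements. A signature built from such gene-pair orderings
can be applied to a **single sample**, with no reference cohort and no
normalization, across platforms.

`reopair` is for computational biologists building or applying this kind of
qualitative signature — the motivating application is distinguishing early
hepatocellular carcinoma (case) from cirrhotic tissue without carcinoma
(control), where biopsy mislocation makes single-sample robustness matter.

## The method

Given a case cohort and a control cohort (gene-by-sample matrices on any
scale):

1. **Stable pairs** — a directed pair (i, j) is stable in a class when
   `x_i > x_j` strictly in ≥ 85% of that class's samples (threshold
   inclusive; ties count toward neither orientation).
2. **Reversal pairs** — stable as `i > j` in cases *and* `j > i` in
   controls; stored in case orientation. These are the candidate features.
3. **Whitelist filtering** — optionally keep pairs whose both genes lie in
   a gene set (e.g. secreted-protein genes, so the signature is
   blood-measurable).
4. **Ternary encoding** — per sample: `0` if `x_i > x_j`, `1` if
   `x_i < x_j`, `-1` otherwise (tie or gene absent from the platform).
5. **Feature ranking** — mRMR (greedy: maximize `MI(f,T)` minus mean
   pairwise `MI(f,f_s)` over the selected set, mutual information in nats)
   or MRMD (|Pearson r| with the class plus mean cosine distance to the
   other features).
6. **Incremental feature selection** — fit a classifier on the top-k pairs
   for k = 1..K; keep the smallest k attaining the maximum accuracy.
   Classifiers: RBF SVM (γ = 2), 1-NN, CART, logistic regression, XGBoost
   (25 rounds, binary-logistic), AdaBoost.M1 on decision stumps, naive
   Bayes.
7. **Evaluation** — Sn, Sp, accuracy, F1 from the confusion counts; AUC via
   the Mann–Whitney identity with a DeLong 95% CI.

The packaged 11-pair signature (`loadBuiltinSignature("mRMR_SVM_11")`,
first pair PCOLCE2|DBH) ships as pairs only — no fitted weights are
published — so applying it means training a classifier on your own or
synthetic cohorts first.

## A worked example

Simulate cohorts with 11 planted reversal pairs (stability 1.0, 200
background genes, 100 case / 50 control), then run discovery and selection:

```r
library(reopair)

sim <- simulateCohorts(nBackgroundGenes = 200, nPlantedPairs = 11,
                       nCase = 100, nControl = 50,
                       stabilityCase = 1, stabilityControl = 1,
                       seed = 20240304)
labs <- sim$labels
stableCase    <- mineStablePairs(sim$matrix, names(labs)[labs == "case"],
                                 0.85, "case")
stableControl <- mineStablePairs(sim$matrix, names(labs)[labs == "control"],
                                 0.85, "control")
rev <- findReversalPairs(stableCase, stableControl)
rev
#> GenePairSet (reversal) with 11 pair(s)
#>   thresholds: case 0.85 / control 0.85
#>   SIGi01|SIGj01, SIGi02|SIGj02, SIGi03|SIGj03, SIGi04|SIGj04, SIGi05|SIGj05, ...

enc <- encodeProfiles(sim$matrix, rev)
ifs <- incrementalFeatureSelection(mrmrRank(enc, labs), enc, labs,
                                   classifierSpec("svm_rbf"))
ifs
#> IFSResult: k_opt = 1 (accuracy = 1.0000 over k = 1..11)

pred <- predict(bestPredictor(ifs), enc)
classificationMetrics(confusionCounts(pred$label, labs[pred$sample_id]))
#> sensitivity specificity    accuracy          f1
#>           1           1           1           1
```

All 11 planted pairs are recovered as reversal pairs with no background
false positives; at stability 1.0 a single pair already separates the
classes perfectly, so IFS stops at k = 1 and the resubstitution metrics are
all 1. Because only orderings are used, rerunning any of this after
`monotoneTransform(sim$matrix, "log2")` (or rank, or positive-affine)
reproduces identical pair sets, encodings and predictions.

`runPipeline(list(matrix = ..., labels = ..., outDir = ...))` runs the same
stages from files and writes pair sets, the encoding, the ranking, the IFS
curve, the fitted model and metrics under the output directory. A thin CLI
over the same functions lives at `inst/scripts/reopair.R`
(`simulate` / `run` / `predict`).

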