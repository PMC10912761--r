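# shared clean cohorts: planted pairs at stability 1 so the all-0 column
# pattern is the pure case profile
cleanSim <- simulateCohorts(nBackgroundGenes = 20, nPlantedPairs = 3,
                            nCase = 20, nControl = 15,
                            stabilityCase = 1, stabilityControl = 1,
                            seed = 77)
cleanEnc <- encodeProfiles(cleanSim$matrix,
                           cleanSim$truth[, c("gene_i", "gene_j")])

test_that("classifierSpec carries the stated defaults and rejects nonsense", {
  sp <- classifierSpec("svm_rbf")
  expect_equal(sp@params$gamma, 2)
  expect_equal(sp@params$cost, 1)
  expect_equal(classifierSpec("xgboost")@params$nrounds, 25)
  expect_equal(classifierSpec("knn")@params$k, 1)
  expect_error(classifierSpec("weka_j48"))
})

test_that("every classifier kind separates a feature that equals the label", {
  cd <- matrix(rep(c(0L, 1L), c(10, 10)), 1)
  em <- encodedFromCodes(cd)
  labs <- setNames(rep(c("case", "control"), each = 10), colnames(em))
  for (kind in c("svm_rbf", "knn", "decision_tree", "logistic_regression",
                 "lmt", "xgboost", "adaboost_stumps", "naive_bayes")) {
    fit <- trainClassifier(em, labs, classifierSpec(kind))
    pred <- predict(fit, em)
    expect_equal(mean(pred$label == labs[pred$sample_id]), 1,
                 info = kind)
    # scores oriented so higher means case
    expect_gt(mean(pred$score[labs == "case"]),
              mean(pred$score[labs == "control"]))
  }
})

test_that("1-NN reproduces training labels on a tie-free training set", {
  set.seed(3)
  cd <- matrix(sample(c(-1L, 0L, 1L), 4 * 12, replace = TRUE), 4, 12)
  cd[1, ] <- rep(c(0L, 1L), each = 6)   # ensure no duplicated conflicting point
  em <- encodedFromCodes(cd)
  labs <- setNames(rep(c("case", "control"), each = 6), colnames(em))
  fit <- trainClassifier(em, labs, classifierSpec("knn", k = 1))
  pred <- predict(fit, em)
  expect_identical(unname(pred$label), unname(labs[pred$sample_id]))
})

test_that("training is deterministic given the spec seed", {
  labs <- cleanSim$labels
  for (kind in c("svm_rbf", "xgboost", "adaboost_stumps")) {
    f1 <- trainClassifier(cleanEnc, labs, classifierSpec(kind, seed = 11))
    f2 <- trainClassifier(cleanEnc, labs, classifierSpec(kind, seed = 11))
    expect_identical(predict(f1, cleanEnc), predict(f2, cleanEnc),
                     info = kind)
  }
})

test_that("training rejects single-class and undersized input", {
  cd <- matrix(c(0L, 1L, 0L, 1L), 1)
  em <- encodedFromCodes(cd)
  allCase <- setNames(rep("case", 4), colnames(em))
  expect_error(trainClassifier(em, allCase, classifierSpec("svm_rbf")),
               "single class")
  oneCtrl <- setNames(c("case", "case", "case", "control"), colnames(em))
  expect_error(trainClassifier(em, oneCtrl, classifierSpec("svm_rbf")),
               "at least 2")
})

test_that("IFS finds k_opt = 1 when the top feature is perfect", {
  labs <- cleanSim$labels
  rk <- mrmrRank(cleanEnc, labs)
  ifs <- incrementalFeatureSelection(rk, cleanEnc, labs,
                                     classifierSpec("svm_rbf"))
  expect_identical(kOpt(ifs), 1L)
  expect_equal(max(ifsCurve(ifs)$value), 1)
})

test_that("IFS picks the smallest k attaining the maximum on a cohort where
           no single or double feature separates but three do", {
  # case and control occupy complementary halves of the 3-bit cube minus
  # the points that make any 1- or 2-feature projection ambiguous
  case <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  ctrl <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  cd <- t(rbind(case, ctrl)); storage.mode(cd) <- "integer"
  em <- encodedFromCodes(cd)
  labs <- setNames(rep(c("case", "control"), each = 4), colnames(em))
  rk <- mrmrRank(em, labs)
  spec <- classifierSpec("svm_rbf")
  ifs <- incrementalFeatureSelection(rk, em, labs, spec)
  # verify the whole curve by direct per-k fits
  for (k in 1:3) {
    sub <- em[pairIds(rk)[seq_len(k)], , drop = FALSE]
    fit <- trainClassifier(sub, labs, spec)
    pred <- predict(fit, sub)
    expect_equal(ifsCurve(ifs)$value[k],
                 mean(pred$label == labs[pred$sample_id]))
  }
  expect_identical(kOpt(ifs), 3L)
  expect_equal(ifsCurve(ifs)$value, c(0.75, 0.75, 1))
})

test_that("IFS curve has K entries in [0, 1] and is seed-reproducible", {
  labs <- cleanSim$labels
  rk <- mrmdRank(cleanEnc, labs)
  ifs1 <- incrementalFeatureSelection(rk, cleanEnc, labs,
                                      classifierSpec("xgboost", seed = 5))
  ifs2 <- incrementalFeatureSelection(rk, cleanEnc, labs,
                                      classifierSpec("xgboost", seed = 5))
  expect_identical(nrow(ifsCurve(ifs1)), nrow(genePairs(rk)))
  expect_true(all(ifsCurve(ifs1)$value >= 0 & ifsCurve(ifs1)$value <= 1))
  expect_identical(ifsCurve(ifs1), ifsCurve(ifs2))
  expect_error(
    incrementalFeatureSelection(rk, cleanEnc, cleanSim$labels,
                                classifierSpec("svm_rbf"), metric = "auc"),
    "arg")
})

test_that("stratified cross-validated IFS runs and stays in range", {
  labs <- cleanSim$labels
  rk <- mrmrRank(cleanEnc, labs, k = 3)
  ifs <- incrementalFeatureSelection(rk, cleanEnc, labs,
                                     classifierSpec("svm_rbf"), cv = 5)
  expect_true(all(ifsCurve(ifs)$value >= 0 & ifsCurve(ifs)$value <= 1))
  expect_identical(kOpt(ifs), 1L)
})

test_that("prediction demands the stored feature list and flags
           all-absent samples", {
  labs <- cleanSim$labels
  fit <- trainClassifier(cleanEnc, labs, classifierSpec("svm_rbf"))
  expect_error(predict(fit, cleanEnc[1:2, ]), "lacks required pair")

  # a sample whose genes are all absent: every code -1, defined label + warning
  mat2 <- cleanSim$matrix
  rownames(mat2) <- paste0("x", rownames(mat2))
  encAbsent <- encodeProfiles(mat2[, 1:2],
                              cleanSim$truth[, c("gene_i", "gene_j")])
  expect_warning(pred <- predict(fit, encAbsent), "absent")
  expect_true(all(pred$label %in% c("case", "control")))
})

test_that("predictions are invariant to monotone per-sample transforms", {
  labs <- cleanSim$labels
  fit <- trainClassifier(cleanEnc, labs, classifierSpec("svm_rbf"))
  base <- predict(fit, cleanEnc)
  for (kind in c("log2", "affine_positive", "rank")) {
    mt <- monotoneTransform(cleanSim$matrix, kind)
    encT <- encodeProfiles(mt, cleanSim$truth[, c("gene_i", "gene_j")])
    expect_identical(predict(fit, encT), base)
  }
})

test_that("swapping class labels preserves accuracy and swaps Sn with Sp", {
  sim <- simulateCohorts(nBackgroundGenes = 10, nPlantedPairs = 2,
                         nCase = 15, nControl = 12,
                         stabilityCase = 0.8, stabilityControl = 0.8,
                         seed = 13)
  enc <- encodeProfiles(sim$matrix, sim$truth[, c("gene_i", "gene_j")])
  labs <- sim$labels
  swapped <- setNames(ifelse(labs == "case", "control", "case"), names(labs))
  spec <- classifierSpec("decision_tree")
  p1 <- predict(trainClassifier(enc, labs, spec), enc)
  p2 <- predict(trainClassifier(enc, swapped, spec), enc)
  m1 <- classificationMetrics(confusionCounts(p1$label, labs[p1$sample_id]))
  m2 <- classificationMetrics(confusionCounts(p2$label, swapped[p2$sample_id]))
  expect_equal(m1[["accuracy"]], m2[["accuracy"]])
  expect_equal(m1[["sensitivity"]], m2[["specificity"]])
  expect_equal(m1[["specificity"]], m2[["sensitivity"]])
})
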