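#' @include io.R reo.R featureRank.R ifs.R metrics.R
NULL

#' Stratified train/test split of a labelled cohort
#'
#' Splits sample ids into a training and a test partition, stratified by
#' class and optionally by a further sample attribute (e.g. specimen type,
#' biopsy vs surgery), so each cell keeps the requested training fraction.
#' Deterministic given the seed; the partition is exact and disjoint.
#'
#' @param labels named \code{case}/\code{control} vector.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param strata optional named vector (same names as \code{labels}) of an
#'   additional stratification attribute.
#' @param seed integer seed.
#' @return list with character vectors \code{train} and \code{test}.
#' @examples
#' labs <- setNames(rep(c("case", "control"), each = 10), paste0("s", 1:20))
#' sp <- splitTrainTest(labs, 0.8, seed = 1)
#' lengths(sp)  # 16 train, 4 test
#' @export
splitTrainTest <- function(labels, fraction = 0.8, strata = NULL,
                           seed = 20240304) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  labs <- .canonLabels(labels)
  cells <- if (is.null(strata)) labs else paste(labs, strata[names(labs)])
  train <- character(0)
  .withSeed(seed, {
    for (cell in sort(unique(cells))) {
      ids <- sort(names(labs)[cells == cell])
      if (!length(ids)) next
      nTrain <- round(fraction * length(ids))
      train <- c(train, sample(ids)[seq_len(nTrain)])
    }
  })
  list(train = sort(train), test = sort(setdiff(names(labs), train)))
}

.rankerFromName <- function(name) {
  switch(tolower(name), mrmr = mrmrRank, mrmd = mrmdRank,
         stop("unknown ranking method: ", name, " (use 'mrmr' or 'mrmd')"))
}

.defaultConfig <- list(threshold = 0.85, ranking = "mrmr",
                       classifier = "svm_rbf", metric = "accuracy", cv = 0,
                       trainFraction = 0.8, seed = 20240304,
                       whitelist = NULL, kMax = NULL)

#' Run the full discovery-to-evaluation workflow
#'
#' Executes, in order: read matrix and labels, stratified train/test split,
#' stable-pair mining in each training class, reversal-pair detection,
#' optional gene-whitelist filtering, ternary encoding, feature ranking
#' (mRMR or MRMD), incremental feature selection with the chosen classifier,
#' and evaluation (resubstitution on the training set, plus held-out metrics
#' when a test fraction remains). Every artifact is written under
#' \code{outDir} along with the run's config (stamped with a content hash),
#' so a rerun with the same config reproduces identical artifacts. Test
#' samples never influence mining, ranking or model fitting.
#'
#' @param config named list or path to a YAML file with fields:
#'   \code{matrix}, \code{labels}, \code{outDir} (required); optional
#'   \code{whitelist} (path), \code{threshold} (0.85), \code{ranking}
#'   ("mrmr"/"mrmd"), \code{classifier} (a \code{\link{classifierSpec}}
#'   kind), \code{metric} ("accuracy"/"f1"), \code{cv} (0 = resubstitution),
#'   \code{trainFraction} (0.8; 1 disables the held-out split), \code{seed},
#'   \code{kMax} (cap on ranked features).
#' @return invisibly, a list with the pair sets, encoded matrix, ranking,
#'   IFS result, metrics and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    .assertFileExists(config, "config")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultConfig, config)
  for (field in c("matrix", "labels", "outDir"))
    if (is.null(cfg[[field]])) stop("config is missing required field: ", field)
  # fail fast on inputs before any compute
  .assertFileExists(cfg$matrix, "expression matrix")
  .assertFileExists(cfg$labels, "label")
  if (!is.null(cfg$whitelist)) .assertFileExists(cfg$whitelist, "whitelist")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  mat <- readExpressionMatrix(cfg$matrix)
  labels <- readCohortLabels(cfg$labels)
  labels <- .canonLabels(labels, colnames(mat))

  cfgLines <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), ""), sep = ": ")
  hash <- .configHash(cfgLines)
  yaml::write_yaml(c(cfg[order(names(cfg))], list(configHash = hash)),
                   file.path(cfg$outDir, "config.yaml"))

  if (cfg$trainFraction < 1) {
    sp <- splitTrainTest(labels, cfg$trainFraction, seed = cfg$seed)
  } else {
    sp <- list(train = names(labels), test = character(0))
  }
  trainLabs <- labels[sp$train]
  caseIds <- names(trainLabs)[trainLabs == "case"]
  controlIds <- names(trainLabs)[trainLabs == "control"]
  if (!length(caseIds) || !length(controlIds))
    stop("both classes must be present in the training set")

  stableCase <- mineStablePairs(mat, caseIds, cfg$threshold, "case")
  stableControl <- mineStablePairs(mat, controlIds, cfg$threshold, "control")
  message("stable pairs: ", length(stableCase), " (case), ",
          length(stableControl), " (control)")
  reversal <- findReversalPairs(stableCase, stableControl)
  message("reversal pairs: ", length(reversal))
  if (!is.null(cfg$whitelist)) {
    wl <- readGeneList(cfg$whitelist)
    reversal <- filterPairsByGeneSet(reversal, wl)
    message("whitelist-filtered pairs: ", length(reversal))
  }
  if (length(reversal) == 0L)
    stop("no reversal pairs survive mining/filtering; nothing to encode")
  writeGenePairs(stableCase, file.path(cfg$outDir, "stable_case.tsv"))
  writeGenePairs(stableControl, file.path(cfg$outDir, "stable_control.tsv"))
  writeGenePairs(reversal, file.path(cfg$outDir, "reversal_pairs.tsv"))

  encodedTrain <- encodeProfiles(mat[, sp$train, drop = FALSE], reversal)
  writeEncodedMatrix(encodedTrain, file.path(cfg$outDir, "encoded_train.tsv"))

  ranker <- .rankerFromName(cfg$ranking)
  kMax <- if (is.null(cfg$kMax)) nrow(encodedTrain)
          else min(cfg$kMax, nrow(encodedTrain))
  ranked <- ranker(encodedTrain, trainLabs, k = kMax)
  writeRanking(ranked, file.path(cfg$outDir, "ranking.tsv"))

  spec <- classifierSpec(cfg$classifier, seed = cfg$seed)
  ifs <- incrementalFeatureSelection(ranked, encodedTrain, trainLabs, spec,
                                     metric = cfg$metric, cv = cfg$cv)
  utils::write.table(ifsCurve(ifs), file.path(cfg$outDir, "ifs_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("IFS: k_opt = ", kOpt(ifs))
  predictor <- bestPredictor(ifs)
  saveRDS(list(package = "reopair", version = "0.1.0", configHash = hash,
               predictor = predictor),
          file.path(cfg$outDir, "model.rds"))

  evalSet <- function(ids, tag) {
    enc <- encodeProfiles(mat[, ids, drop = FALSE],
                          genePairs(encodedTrain)[
                            match(predictor@featureIds, rownames(encodedTrain)),
                            , drop = FALSE])
    pred <- suppressWarnings(predict(predictor, enc))
    truth <- labels[pred$sample_id]
    cc <- confusionCounts(pred$label, truth)
    rep <- as.list(classificationMetrics(cc))
    if (length(unique(truth)) == 2L) {
      auc <- rocAucCI(pred$score, truth)
      rep <- c(rep, list(auc = auc$auc, auc_ci_low = auc$ciLow,
                         auc_ci_high = auc$ciHigh))
    }
    writeMetrics(rep, file.path(cfg$outDir, paste0("metrics_", tag, ".tsv")),
                 file.path(cfg$outDir, paste0("metrics_", tag, ".json")))
    rep
  }
  metricsTrain <- evalSet(sp$train, "train")
  metricsTest <- if (length(sp$test)) evalSet(sp$test, "test") else NULL

  invisible(list(config = cfg, configHash = hash, split = sp,
                 stableCase = stableCase, stableControl = stableControl,
                 reversalPairs = reversal, encodedTrain = encodedTrain,
                 ranking = ranked, ifs = ifs, predictor = predictor,
                 metricsTrain = metricsTrain, metricsTest = metricsTest,
                 outDir = cfg$outDir))
}
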