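#' @include classifiers.R metrics.R
NULL

.metricFromPrediction <- function(predicted, truth, metric) {
  cc <- confusionCounts(predicted, truth)
  unname(classificationMetrics(cc, metrics = metric))
}

# deterministic stratified fold assignment: per class, shuffle then deal
# round-robin into nFolds
.stratifiedFolds <- function(labs, nFolds, seed) {
  fold <- integer(length(labs))
  names(fold) <- names(labs)
  .withSeed(seed, {
    for (cl in unique(labs)) {
      ids <- sample(names(labs)[labs == cl])
      fold[ids] <- rep_len(seq_len(nFolds), length(ids))
    }
  })
  fold
}

#' Incremental feature selection over a ranked feature list
#'
#' For k = 1..K fits the classifier on the top-k ranked features and records
#' the evaluation metric; the optimum is the smallest k attaining the curve
#' maximum, and the returned predictor is refitted on those k features. The
#' default protocol evaluates on the training samples themselves
#' (resubstitution); \code{cv > 1} switches to stratified k-fold
#' cross-validation with deterministic, seeded fold assignment.
#'
#' @param ranked a \linkS4class{RankedGenePairs}.
#' @param encoded an \linkS4class{EncodedMatrix} containing (at least) the
#'   ranked features.
#' @param labels named \code{case}/\code{control} vector.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param metric \code{"accuracy"} (default) or \code{"f1"}.
#' @param cv 0 for resubstitution (default) or the number of folds.
#' @return an \linkS4class{IFSResult}.
#' @export
incrementalFeatureSelection <- function(ranked, encoded, labels, spec,
                                        metric = c("accuracy", "f1"),
                                        cv = 0) {
  metric <- match.arg(metric)
  stopifnot(is(ranked, "RankedGenePairs"))
  ids <- pairIds(ranked)
  if (!length(ids)) stop("ranked feature list is empty")
  absent <- setdiff(ids, rownames(encoded))
  if (length(absent))
    stop("ranked feature(s) absent from encoded matrix: ",
         paste(absent, collapse = ", "))
  labs <- .canonLabels(labels)
  labs <- labs[colnames(encoded)]
  K <- length(ids)
  vals <- numeric(K)
  folds <- if (cv > 1) .stratifiedFolds(labs, cv, spec@seed) else NULL
  for (k in seq_len(K)) {
    sub <- encoded[ids[seq_len(k)], , drop = FALSE]
    if (is.null(folds)) {
      fit <- trainClassifier(sub, labs, spec)
      pred <- suppressWarnings(predict(fit, sub))
      vals[k] <- .metricFromPrediction(pred$label, labs[pred$sample_id], metric)
    } else {
      predAll <- character(length(labs)); names(predAll) <- names(labs)
      for (f in seq_len(cv)) {
        trainIds <- names(folds)[folds != f]
        testIds <- names(folds)[folds == f]
        fit <- trainClassifier(sub[, trainIds], labs[trainIds], spec)
        pred <- suppressWarnings(predict(fit, sub[, testIds, drop = FALSE]))
        predAll[pred$sample_id] <- pred$label
      }
      vals[k] <- .metricFromPrediction(predAll, labs[names(predAll)], metric)
    }
  }
  kBest <- which.max(vals)   # which.max returns the smallest k at the max
  predictor <- trainClassifier(encoded[ids[seq_len(kBest)], , drop = FALSE],
                               labs, spec)
  new("IFSResult", curve = data.frame(k = seq_len(K), value = vals),
      metric = metric, kOpt = as.integer(kBest), predictor = predictor)
}
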