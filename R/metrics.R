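#' @include utils.R
NULL

#' Confusion counts for case/control predictions
#'
#' Positives are case samples, negatives control. Counts are exact integers:
#' TP + FN = number of true cases, TN + FP = number of true controls.
#'
#' @param predicted,truth equal-length vectors with values \code{"case"} or
#'   \code{"control"}.
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @examples
#' confusionCounts(c("case", "case", "control", "control"),
#'                 c("case", "case", "control", "control"))
#' @export
confusionCounts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(predicted) < 1L) stop("empty inputs")
  predicted <- as.character(predicted); truth <- as.character(truth)
  bad <- setdiff(unique(c(predicted, truth)), c("case", "control"))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  c(TP = sum(predicted == "case" & truth == "case"),
    FP = sum(predicted == "case" & truth == "control"),
    TN = sum(predicted == "control" & truth == "control"),
    FN = sum(predicted == "control" & truth == "case"))
}

#' Sensitivity, specificity, accuracy and F1 from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n, F1 = 2TP/(2TP+FP+FN).
#' A requested metric whose denominator is zero raises an error rather than
#' silently returning NaN; request only the defined ones (e.g.
#' \code{metrics = "sensitivity"} for a case-only validation cohort).
#'
#' @param cc named counts from \code{\link{confusionCounts}}.
#' @param metrics which metrics to compute.
#' @return named numeric vector in [0, 1].
#' @examples
#' classificationMetrics(c(TP = 3, FP = 2, TN = 2, FN = 1))
#' @export
classificationMetrics <- function(cc,
    metrics = c("sensitivity", "specificity", "accuracy", "f1")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(cc))) stop("cc needs named counts TP, FP, TN, FN")
  TP <- cc[["TP"]]; FP <- cc[["FP"]]; TN <- cc[["TN"]]; FN <- cc[["FN"]]
  P <- TP + FN; N <- TN + FP
  out <- numeric(0)
  for (m in metrics) {
    v <- switch(m,
      sensitivity = {
        if (P == 0) stop("sensitivity undefined: no positive samples")
        TP / P
      },
      specificity = {
        if (N == 0) stop("specificity undefined: no negative samples")
        TN / N
      },
      accuracy = (TP + TN) / (TP + FP + TN + FN),
      f1 = {
        if (2 * TP + FP + FN == 0) stop("F1 undefined: no positive calls or samples")
        2 * TP / (2 * TP + FP + FN)
      })
    out[m] <- v
  }
  out
}

#' Empirical AUC with a 95\% confidence interval
#'
#' AUC is the area under the empirical ROC (FPR on the x-axis, TPR on the
#' y-axis), computed via the rank/Mann-Whitney identity with half credit for
#' score ties; higher scores must indicate case. The confidence interval is
#' DeLong's analytic interval by default (deterministic), or a seeded
#' stratified bootstrap, both delegated to \pkg{pROC} and truncated to
#' [0, 1].
#'
#' @param scores numeric scores, higher = more case-like.
#' @param truth equal-length vector of \code{"case"}/\code{"control"}; both
#'   classes must be present.
#' @param alpha 1 - confidence level (default 0.05 for a 95\% CI).
#' @param method \code{"delong"} (default) or \code{"bootstrap"}.
#' @param bootN bootstrap resamples when \code{method = "bootstrap"}.
#' @param seed seed for the bootstrap.
#' @return list with \code{auc}, \code{ciLow}, \code{ciHigh}.
#' @export
rocAucCI <- function(scores, truth, alpha = 0.05,
                     method = c("delong", "bootstrap"), bootN = 2000,
                     seed = 20240304) {
  method <- match.arg(method)
  if (length(scores) != length(truth)) stop("length mismatch")
  truth <- as.character(truth)
  bad <- setdiff(unique(truth), c("case", "control"))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  nCase <- sum(truth == "case"); nCtrl <- sum(truth == "control")
  if (nCase == 0L || nCtrl == 0L)
    stop("AUC undefined: both classes must be present")
  # Mann-Whitney via midranks: ties get half credit automatically
  r <- rank(scores)
  auc <- (sum(r[truth == "case"]) - nCase * (nCase + 1) / 2) / (nCase * nCtrl)
  rocObj <- pROC::roc(response = truth, predictor = scores,
                      levels = c("control", "case"), direction = "<",
                      quiet = TRUE)
  ci <- .withSeed(if (method == "bootstrap") seed else NULL,
    pROC::ci.auc(rocObj, conf.level = 1 - alpha, method = method,
                 boot.n = bootN))
  list(auc = auc, ciLow = max(0, as.numeric(ci[1L])),
       ciHigh = min(1, as.numeric(ci[3L])))
}

#' Points of the empirical ROC curve
#'
#' One row per distinct score threshold, suitable for export or plotting:
#' FPR (x), TPR (y) and the threshold at which they are attained.
#'
#' @inheritParams rocAucCI
#' @return data.frame with columns \code{fpr}, \code{tpr}, \code{threshold}.
#' @export
rocPoints <- function(scores, truth) {
  truth <- as.character(truth)
  nCase <- sum(truth == "case"); nCtrl <- sum(truth == "control")
  if (nCase == 0L || nCtrl == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == "case") / nCase, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == "control") / nCtrl, 0)
  data.frame(fpr = fpr, tpr = tpr, threshold = thr)
}

#' Write a metrics report as TSV and/or JSON
#'
#' @param report named numeric vector or list of metric values.
#' @param pathTsv,pathJson output paths (either may be NULL).
#' @return invisibly, the report.
#' @export
writeMetrics <- function(report, pathTsv = NULL, pathJson = NULL) {
  rep <- as.list(report)
  if (!is.null(pathTsv))
    utils::write.table(
      data.frame(metric = names(rep), value = unlist(rep)),
      pathTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathJson))
    jsonlite::write_json(rep, pathJson, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
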