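#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# GenePairSet

#' Set of directed gene pairs
#'
#' A \code{GenePairSet} holds directed gene pairs \code{(gene_i, gene_j)}
#' together with their provenance: \code{"stable"} sets record pairs with
#' \code{gene_i > gene_j} in at least \code{threshold} of one class's
#' samples; \code{"reversal"} sets record pairs stable as \code{gene_i >
#' gene_j} in the case class and as \code{gene_j > gene_i} in the control
#' class (canonical orientation: gene_i is the gene higher in cases).
#'
#' @slot pairs data.frame with character columns \code{gene_i}, \code{gene_j}.
#' @slot type \code{"stable"} or \code{"reversal"}.
#' @slot classLabel class the set was mined in (\code{NA} for reversal sets).
#' @slot threshold stability threshold(s) used; named \code{c(case=, control=)}
#'   for reversal sets.
#'
#' @aliases GenePairSet-class
#' @export
setClass("GenePairSet",
  representation(pairs = "data.frame", type = "character",
                 classLabel = "character", threshold = "numeric"),
  prototype(pairs = data.frame(gene_i = character(), gene_j = character(),
                               stringsAsFactors = FALSE),
            type = "stable", classLabel = NA_character_, threshold = 0.85))

setValidity("GenePairSet", function(object) {
  p <- object@pairs
  if (!all(c("gene_i", "gene_j") %in% names(p)))
    return("pairs must have columns gene_i and gene_j")
  if (nrow(p)) {
    if (any(p$gene_i == p$gene_j))
      return("self-pairs (gene_i == gene_j) are not allowed")
    unord <- paste(pmin(p$gene_i, p$gene_j), pmax(p$gene_i, p$gene_j))
    if (anyDuplicated(unord))
      return("an unordered pair may appear under exactly one orientation")
  }
  if (!object@type %in% c("stable", "reversal"))
    return("type must be 'stable' or 'reversal'")
  if (any(object@threshold <= 0.5 | object@threshold > 1))
    return("threshold must lie in (0.5, 1]")
  TRUE
})

#' Construct a GenePairSet
#'
#' @param pairs data.frame with columns \code{gene_i}, \code{gene_j}.
#' @param type \code{"stable"} or \code{"reversal"}.
#' @param classLabel class in which the set was mined.
#' @param threshold stability threshold(s) in (0.5, 1].
#' @return A \linkS4class{GenePairSet}.
#' @export
GenePairSet <- function(pairs, type = "stable", classLabel = NA_character_,
                        threshold = 0.85) {
  pairs <- data.frame(gene_i = as.character(pairs$gene_i),
                      gene_j = as.character(pairs$gene_j),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("GenePairSet", pairs = pairs, type = type,
      classLabel = as.character(classLabel), threshold = threshold)
}

# ---------------------------------------------------------------------------
# EncodedMatrix

#' Ternary pair-by-sample encoding
#'
#' An \code{EncodedMatrix} extends \link[SummarizedExperiment]{SummarizedExperiment}:
#' rows are gene pairs (rownames \code{"genei|genej"}, with \code{gene_i} and
#' \code{gene_j} in \code{rowData}), columns are samples, and the single
#' assay \code{"codes"} holds per-sample ordering codes: \code{0} when
#' \code{gene_i > gene_j}, \code{1} when \code{gene_i < gene_j}, and
#' \code{-1} otherwise (tie, or a gene absent from the platform).
#'
#' @aliases EncodedMatrix-class
#' @export
setClass("EncodedMatrix", contains = "SummarizedExperiment")

setValidity("EncodedMatrix", function(object) {
  if (!identical(SummarizedExperiment::assayNames(object), "codes"))
    return("EncodedMatrix must carry exactly one assay named 'codes'")
  cd <- SummarizedExperiment::assay(object, "codes")
  if (!all(cd %in% c(-1L, 0L, 1L)))
    return("codes must be in {-1, 0, 1}")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_i", "gene_j") %in% colnames(rd)))
    return("rowData must carry gene_i and gene_j")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("rownames must be unique pair ids")
  TRUE
})

#' Construct an EncodedMatrix from a code matrix and its pairs
#'
#' @param codes integer matrix with values in \code{{-1, 0, 1}}; one row per
#'   pair, one column per sample.
#' @param pairs data.frame with columns \code{gene_i}, \code{gene_j}, one row
#'   per row of \code{codes}.
#' @return An \linkS4class{EncodedMatrix}.
#' @export
EncodedMatrix <- function(codes, pairs) {
  storage.mode(codes) <- "integer"
  rownames(codes) <- .pairId(pairs$gene_i, pairs$gene_j)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(codes = codes),
    rowData = S4Vectors::DataFrame(gene_i = as.character(pairs$gene_i),
                                   gene_j = as.character(pairs$gene_j)))
  new("EncodedMatrix", se)
}

# ---------------------------------------------------------------------------
# RankedGenePairs

#' Ranked pair-features
#'
#' Output of \code{\link{mrmrRank}} / \code{\link{mrmdRank}}: gene pairs in
#' decreasing order of the method's selection score.
#'
#' @slot ranking data.frame with columns \code{rank}, \code{pair_id},
#'   \code{gene_i}, \code{gene_j}, \code{score}.
#' @slot method \code{"mRMR"} or \code{"MRMD"}.
#' @aliases RankedGenePairs-class
#' @export
setClass("RankedGenePairs",
  representation(ranking = "data.frame", method = "character"))

setValidity("RankedGenePairs", function(object) {
  r <- object@ranking
  need <- c("rank", "pair_id", "gene_i", "gene_j", "score")
  if (!all(need %in% names(r)))
    return(paste("ranking needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$pair_id)) return("duplicate features in ranking")
  if (nrow(r) && !identical(r$rank, seq_len(nrow(r))))
    return("rank must be 1..K in order")
  if (!object@method %in% c("mRMR", "MRMD"))
    return("method must be 'mRMR' or 'MRMD'")
  TRUE
})

# ---------------------------------------------------------------------------
# ClassifierSpec / TrainedPredictor / IFSResult

#' Classifier specification
#'
#' @slot kind one of \code{svm_rbf}, \code{knn}, \code{decision_tree},
#'   \code{logistic_regression}, \code{lmt} (logistic-regression stand-in for
#'   Weka's logistic model trees), \code{xgboost}, \code{adaboost_stumps},
#'   \code{naive_bayes}.
#' @slot params named list of hyperparameters.
#' @slot seed integer seed applied before any stochastic fit.
#' @aliases ClassifierSpec-class
#' @export
setClass("ClassifierSpec",
  representation(kind = "character", params = "list", seed = "numeric"))

.CLASSIFIER_KINDS <- c("svm_rbf", "knn", "decision_tree",
                       "logistic_regression", "lmt", "xgboost",
                       "adaboost_stumps", "naive_bayes")

setValidity("ClassifierSpec", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% .CLASSIFIER_KINDS)
    return(paste("kind must be one of:", paste(.CLASSIFIER_KINDS, collapse = ", ")))
  TRUE
})

#' Fitted gene-pair classifier
#'
#' @slot spec the \linkS4class{ClassifierSpec} it was fitted with.
#' @slot featureIds pair ids the model expects, in training order.
#' @slot fit fitted model object (kind-specific).
#' @slot classLevels always \code{c("control", "case")}.
#' @slot trainPrevalence fraction of case samples in the training set.
#' @slot orientation +1/-1 multiplier making higher scores mean case.
#' @aliases TrainedPredictor-class
#' @export
setClass("TrainedPredictor",
  representation(spec = "ClassifierSpec", featureIds = "character",
                 fit = "ANY", classLevels = "character",
                 trainPrevalence = "numeric", orientation = "numeric"))

#' Incremental feature selection result
#'
#' @slot curve data.frame with columns \code{k} and \code{metric} value.
#' @slot metric metric name the curve records.
#' @slot kOpt smallest k attaining the curve maximum.
#' @slot predictor \linkS4class{TrainedPredictor} refitted on the top
#'   \code{kOpt} features.
#' @aliases IFSResult-class
#' @export
setClass("IFSResult",
  representation(curve = "data.frame", metric = "character",
                 kOpt = "integer", predictor = "TrainedPredictor"))

setValidity("IFSResult", function(object) {
  if (!all(c("k", "value") %in% names(object@curve)))
    return("curve needs columns k and value")
  if (length(object@kOpt) != 1L || object@kOpt < 1L)
    return("kOpt must be a single positive integer")
  TRUE
})

# ---------------------------------------------------------------------------
# GenePairSignature

#' Fixed gene-pair signature
#'
#' An ordered panel of gene pairs in canonical orientation (gene_i higher in
#' the case class), applicable to one sample at a time.
#'
#' @slot name signature identifier.
#' @slot pairs data.frame with columns \code{gene_i}, \code{gene_j}.
#' @slot note free-text provenance note.
#' @aliases GenePairSignature-class
#' @export
setClass("GenePairSignature",
  representation(name = "character", pairs = "data.frame", note = "character"))

setValidity("GenePairSignature", function(object) {
  p <- object@pairs
  if (!all(c("gene_i", "gene_j") %in% names(p)))
    return("pairs must have columns gene_i and gene_j")
  if (nrow(p) < 1L) return("a signature needs at least one pair")
  unord <- paste(pmin(p$gene_i, p$gene_j), pmax(p$gene_i, p$gene_j))
  if (anyDuplicated(unord)) return("duplicate unordered pair in signature")
  TRUE
})

#' Construct a GenePairSignature
#'
#' @param name signature identifier.
#' @param pairs data.frame with columns \code{gene_i}, \code{gene_j} in rank
#'   order.
#' @param note provenance note.
#' @return A \linkS4class{GenePairSignature}.
#' @export
GenePairSignature <- function(name, pairs, note = "") {
  pairs <- data.frame(gene_i = as.character(pairs$gene_i),
                      gene_j = as.character(pairs$gene_j),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("GenePairSignature", name = name, pairs = pairs, note = note)
}
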