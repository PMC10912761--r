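#' @include AllClasses.R
NULL

#' Gene pairs of an object
#' @param x a GenePairSet, EncodedMatrix, RankedGenePairs or GenePairSignature.
#' @return data.frame with columns \code{gene_i}, \code{gene_j} (plus scores
#'   for ranked lists).
#' @export
setGeneric("genePairs", function(x) standardGeneric("genePairs"))

#' Pair ids ("genei|genej") of an object, in its stored order
#' @param x a GenePairSet, EncodedMatrix, RankedGenePairs or GenePairSignature.
#' @return character vector of pair ids.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' Ternary code matrix of an EncodedMatrix
#' @param x an EncodedMatrix.
#' @return integer matrix with values in \code{{-1, 0, 1}}.
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' Type of a GenePairSet ("stable" or "reversal")
#' @param x a GenePairSet.
#' @return character scalar.
#' @export
setGeneric("pairType", function(x) standardGeneric("pairType"))

#' Per-k metric curve of an IFS run
#' @param x an IFSResult.
#' @return data.frame with columns \code{k} and \code{value}.
#' @export
setGeneric("ifsCurve", function(x) standardGeneric("ifsCurve"))

#' Optimal feature count of an IFS run
#' @param x an IFSResult.
#' @return integer: smallest k attaining the curve maximum.
#' @export
setGeneric("kOpt", function(x) standardGeneric("kOpt"))

#' Predictor refitted at the optimal k of an IFS run
#' @param x an IFSResult.
#' @return a TrainedPredictor.
#' @export
setGeneric("bestPredictor", function(x) standardGeneric("bestPredictor"))

# -- methods ----------------------------------------------------------------

#' @describeIn genePairs pairs of a GenePairSet
#' @export
setMethod("genePairs", "GenePairSet", function(x) x@pairs)

#' @describeIn genePairs pairs of an EncodedMatrix (from rowData)
#' @export
setMethod("genePairs", "EncodedMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(gene_i = rd$gene_i, gene_j = rd$gene_j, stringsAsFactors = FALSE)
})

#' @describeIn genePairs ranked pairs with scores
#' @export
setMethod("genePairs", "RankedGenePairs", function(x) x@ranking)

#' @describeIn genePairs pairs of a signature, in rank order
#' @export
setMethod("genePairs", "GenePairSignature", function(x) x@pairs)

#' @describeIn pairIds pair ids of a GenePairSet
#' @export
setMethod("pairIds", "GenePairSet",
          function(x) .pairId(x@pairs$gene_i, x@pairs$gene_j))

#' @describeIn pairIds rownames of an EncodedMatrix
#' @export
setMethod("pairIds", "EncodedMatrix", function(x) rownames(x))

#' @describeIn pairIds pair ids in rank order
#' @export
setMethod("pairIds", "RankedGenePairs", function(x) x@ranking$pair_id)

#' @describeIn pairIds pair ids of a signature
#' @export
setMethod("pairIds", "GenePairSignature",
          function(x) .pairId(x@pairs$gene_i, x@pairs$gene_j))

#' @describeIn codes code matrix accessor
#' @export
setMethod("codes", "EncodedMatrix",
          function(x) SummarizedExperiment::assay(x, "codes"))

#' @describeIn pairType type accessor
#' @export
setMethod("pairType", "GenePairSet", function(x) x@type)

#' @describeIn ifsCurve curve accessor
#' @export
setMethod("ifsCurve", "IFSResult", function(x) x@curve)

#' @describeIn kOpt kOpt accessor
#' @export
setMethod("kOpt", "IFSResult", function(x) x@kOpt)

#' @describeIn bestPredictor predictor accessor
#' @export
setMethod("bestPredictor", "IFSResult", function(x) x@predictor)

#' Number of pairs in a GenePairSet
#' @param x a GenePairSet.
#' @return integer.
#' @export
setMethod("length", "GenePairSet", function(x) nrow(x@pairs))

#' Number of pairs in a signature
#' @param x a GenePairSignature.
#' @return integer.
#' @export
setMethod("length", "GenePairSignature", function(x) nrow(x@pairs))

# -- show -------------------------------------------------------------------

setMethod("show", "GenePairSet", function(object) {
  cat(sprintf("GenePairSet (%s) with %d pair(s)\n", object@type,
              nrow(object@pairs)))
  if (object@type == "stable")
    cat(sprintf("  class: %s, threshold: %g\n", object@classLabel,
                object@threshold[1]))
  else
    cat(sprintf("  thresholds: case %g / control %g\n",
                object@threshold[["case"]], object@threshold[["control"]]))
  if (nrow(object@pairs)) {
    shown <- utils::head(.pairId(object@pairs$gene_i, object@pairs$gene_j), 5)
    cat("  ", paste(shown, collapse = ", "),
        if (nrow(object@pairs) > 5) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "RankedGenePairs", function(object) {
  cat(sprintf("RankedGenePairs: %d feature(s) ranked by %s\n",
              nrow(object@ranking), object@method))
  print(utils::head(object@ranking, 5))
  if (nrow(object@ranking) > 5) cat("  ...\n")
})

setMethod("show", "ClassifierSpec", function(object) {
  ps <- if (length(object@params))
    paste(names(object@params), vapply(object@params, format, ""),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("ClassifierSpec: %s (%s), seed %g\n", object@kind, ps,
              object@seed))
})

setMethod("show", "TrainedPredictor", function(object) {
  cat(sprintf("TrainedPredictor: %s on %d pair feature(s)\n",
              object@spec@kind, length(object@featureIds)))
  cat(sprintf("  training case prevalence: %.3f\n", object@trainPrevalence))
})

setMethod("show", "IFSResult", function(object) {
  cat(sprintf("IFSResult: k_opt = %d (%s = %.4f over k = 1..%d)\n",
              object@kOpt, object@metric,
              max(object@curve$value), nrow(object@curve)))
})

setMethod("show", "GenePairSignature", function(object) {
  cat(sprintf("GenePairSignature '%s' with %d pair(s)\n", object@name,
              nrow(object@pairs)))
  if (nzchar(object@note)) cat("  note: ", object@note, "\n", sep = "")
})
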