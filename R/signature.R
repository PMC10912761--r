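#' @include AllClasses.R reo.R classifiers.R
NULL

# registry of packaged signatures; MRMD_SVM_28 is registered but not shipped:
# its pairs are published only in supplementary material we do not reproduce
.SIGNATURE_REGISTRY <- list(
  mRMR_SVM_11 = list(
    file = "signatures/mRMR_SVM_11.tsv",
    note = paste("11 gene pairs (18 secreted genes) selected by mRMR ranking",
                 "with an RBF-SVM over reversal pairs between hepatocellular",
                 "carcinoma and cirrhosis-without-HCC cohorts; orientation:",
                 "gene_i is expressed above gene_j in HCC.")),
  MRMD_SVM_28 = list(
    file = NA_character_,
    note = paste("28-pair MRMD-ranked companion signature; its pair list is",
                 "published only in supplementary material and is not",
                 "packaged. Supply it as a TSV via readSignature()."))
)

#' Load a packaged gene-pair signature
#'
#' The \code{"mRMR_SVM_11"} fixture holds the 11-pair hepatocellular
#' carcinoma signature in rank order, first pair PCOLCE2|DBH, last pair
#' KDSR|ASAH1. Note the fixture provides the pairs only, not fitted SVM
#' weights (none are published): applying it requires training a classifier
#' on your own or synthetic cohorts first.
#'
#' @param name registered signature name.
#' @return a \linkS4class{GenePairSignature}.
#' @examples
#' sig <- loadBuiltinSignature("mRMR_SVM_11")
#' length(sig)  # 11
#' @export
loadBuiltinSignature <- function(name) {
  if (!name %in% names(.SIGNATURE_REGISTRY))
    stop("unknown signature '", name, "'; available: ",
         paste(names(.SIGNATURE_REGISTRY), collapse = ", "))
  entry <- .SIGNATURE_REGISTRY[[name]]
  if (is.na(entry$file))
    stop("signature '", name, "' is registered but not packaged: ", entry$note)
  path <- system.file("extdata", entry$file, package = "reopair",
                      mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  GenePairSignature(name, df[, c("gene_i", "gene_j")], note = entry$note)
}

#' Read a signature from TSV (rank, gene_i, gene_j)
#' @param path path to the signature TSV.
#' @param name name to record (default: file name).
#' @param note provenance note.
#' @return a \linkS4class{GenePairSignature}.
#' @export
readSignature <- function(path, name = basename(path), note = "") {
  .assertFileExists(path, "signature")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("gene_i", "gene_j") %in% names(df)))
    stop("signature TSV needs columns gene_i and gene_j")
  if ("rank" %in% names(df)) df <- df[order(as.integer(df$rank)), ]
  GenePairSignature(name, df[, c("gene_i", "gene_j")], note = note)
}

#' Write a signature as TSV (rank, gene_i, gene_j)
#' @param sig a \linkS4class{GenePairSignature}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSignature <- function(sig, path) {
  p <- genePairs(sig)
  utils::write.table(
    data.frame(rank = seq_len(nrow(p)), gene_i = p$gene_i, gene_j = p$gene_j),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a fixed gene-pair signature to individual samples
#'
#' Encodes each sample of the expression matrix against the signature's pairs
#' (a per-sample operation: only within-sample orderings are used, so any
#' monotone per-sample transform of the input leaves the output unchanged and
#' no between-sample information enters) and predicts with a classifier
#' fitted on exactly those pairs.
#'
#' @param mat numeric gene-by-sample matrix; genes absent from the matrix
#'   encode as -1.
#' @param sig a \linkS4class{GenePairSignature}.
#' @param predictor a \linkS4class{TrainedPredictor} fitted on exactly the
#'   signature's pairs, in order.
#' @return data.frame with columns \code{sample_id}, \code{label},
#'   \code{score}.
#' @export
applySignature <- function(mat, sig, predictor) {
  stopifnot(is(sig, "GenePairSignature"), is(predictor, "TrainedPredictor"))
  if (!identical(pairIds(sig), predictor@featureIds))
    stop("predictor was not fitted on this signature's pairs ",
         "(feature lists differ)")
  encoded <- encodeProfiles(mat, sig)
  predict(predictor, encoded)
}
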