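#' @include utils.R
NULL

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects tab-separated text with one header line. By default genes are in
#' rows: the header holds sample ids and the first column gene (or probe)
#' ids, the GEO series-matrix convention. Values may be on any linear or log
#' scale; only within-sample orderings are ever used downstream.
#'
#' @param path path to a TSV file.
#' @param genesIn \code{"rows"} (default) or \code{"columns"}.
#' @param probeToGene optional named character vector mapping probe ids to
#'   gene symbols; when supplied, rows are collapsed to gene level with
#'   \code{\link{collapseProbes}} after reading (and duplicate row ids are
#'   then permitted).
#' @return numeric matrix, genes in rows, samples in columns.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tsv)
#' readExpressionMatrix(tsv)
#' @export
readExpressionMatrix <- function(path, genesIn = c("rows", "columns"),
                                 probeToGene = NULL) {
  genesIn <- match.arg(genesIn)
  .assertFileExists(path, "expression matrix")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression matrix needs an id column plus >=1 sample")
  rowIds <- df[[1L]]
  colIds <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    b <- bad[1L] - 1L
    r <- b %% nrow(body) + 1L
    cc <- b %/% nrow(body) + 1L
    stop(sprintf("non-numeric or non-finite value '%s' at row '%s', column '%s'",
                 body[r, cc], rowIds[r], colIds[cc]))
  }
  mat <- matrix(vals, nrow = nrow(body), dimnames = list(rowIds, colIds))
  if (genesIn == "columns") mat <- t(mat)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (!is.null(probeToGene)) {
    mat <- collapseProbes(mat, probeToGene)
  } else if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         "; supply probeToGene to collapse probes")
  }
  mat
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param mat numeric matrix, genes in rows.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level by arithmetic mean
#'
#' Each output gene row is the per-sample arithmetic mean of the probe rows
#' mapped to it. Probes absent from the map are dropped with a message;
#' microarray platform maps are always partial.
#'
#' @param mat numeric matrix, probes in rows.
#' @param probeToGene named character vector: names are probe ids, values
#'   gene symbols.
#' @return numeric matrix with unique gene rownames.
#' @examples
#' m <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' collapseProbes(m, c(p1 = "G", p2 = "G"))  # G = 3
#' @export
collapseProbes <- function(mat, probeToGene) {
  if (length(probeToGene) == 0L) stop("probe-to-gene map is empty")
  if (is.null(names(probeToGene))) stop("probeToGene must be named by probe id")
  keep <- rownames(mat) %in% names(probeToGene)
  dropped <- sum(!keep)
  if (dropped)
    message(dropped, " unmapped probe(s) dropped")
  if (!any(keep)) stop("no probe in the matrix is present in the map")
  sub <- mat[keep, , drop = FALSE]
  genes <- unname(probeToGene[rownames(sub)])
  sums <- rowsum(sub, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  sums / counts
}

#' Read a two-column sample label file
#'
#' TSV with header \code{sample_id} and \code{class}; class values must be
#' \code{case} or \code{control}.
#'
#' @param path path to the label TSV.
#' @return named character vector of \code{"case"}/\code{"control"}, named by
#'   sample id.
#' @export
readCohortLabels <- function(path) {
  .assertFileExists(path, "label")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns: sample_id, class")
  .canonLabels(df[, 1:2])
}

#' Write sample labels as two-column TSV
#' @param labels named character vector of \code{"case"}/\code{"control"}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCohortLabels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), class = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines are ignored; duplicates are removed with a message. Matching
#' downstream is exact and case-sensitive unless \code{caseInsensitive}.
#'
#' @param path path to the gene list.
#' @param caseInsensitive fold symbols to upper case.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path, caseInsensitive = FALSE) {
  .assertFileExists(path, "gene list")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("gene list is empty: ", path)
  if (caseInsensitive) lines <- toupper(lines)
  ndup <- sum(duplicated(lines))
  if (ndup) message(ndup, " duplicate gene symbol(s) removed")
  unique(lines)
}

#' Write a GenePairSet as 3-column TSV (gene_i, gene_j, direction)
#' @param x a \linkS4class{GenePairSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenePairs <- function(x, path) {
  p <- genePairs(x)
  utils::write.table(
    data.frame(gene_i = p$gene_i, gene_j = p$gene_j, direction = "GREATER"),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column gene-pair TSV back into a GenePairSet
#' @param path path to the TSV written by \code{\link{writeGenePairs}}.
#' @param type \code{"stable"} or \code{"reversal"}.
#' @param threshold stability threshold(s) to record.
#' @return a \linkS4class{GenePairSet}.
#' @export
readGenePairs <- function(path, type = "reversal",
                          threshold = c(case = 0.85, control = 0.85)) {
  .assertFileExists(path, "gene-pair")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  GenePairSet(df, type = type, threshold = threshold)
}

#' Write an EncodedMatrix as integer TSV (pair ids in rows)
#' @param x an \linkS4class{EncodedMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEncodedMatrix <- function(x, path) {
  df <- data.frame(pair_id = rownames(x), codes(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EncodedMatrix written by \code{\link{writeEncodedMatrix}}
#' @param path path to the TSV.
#' @return an \linkS4class{EncodedMatrix}.
#' @export
readEncodedMatrix <- function(path) {
  .assertFileExists(path, "encoded matrix")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  cd <- as.matrix(df[, -1L, drop = FALSE])
  EncodedMatrix(cd, .splitPairId(as.character(df[[1L]])))
}

#' Write a ranked feature list as TSV (rank, gene_i, gene_j, score, method)
#' @param x a \linkS4class{RankedGenePairs}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRanking <- function(x, path) {
  r <- x@ranking
  utils::write.table(
    data.frame(rank = r$rank, gene_i = r$gene_i, gene_j = r$gene_j,
               score = r$score, method = x@method),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
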