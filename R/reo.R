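#' @include AllClasses.R
NULL

#' Ordering state of one gene pair in one sample
#'
#' Strict comparison of two expression values: \code{GREATER} when
#' \code{x_i > x_j}, \code{LESS} when \code{x_i < x_j}, \code{TIE} on exact
#' equality. Vectorized over both arguments.
#'
#' @param x_i,x_j finite numeric expression values.
#' @return character vector in \code{c("GREATER", "LESS", "TIE")}.
#' @examples
#' pairState(5, 3)   # GREATER
#' pairState(3, 3)   # TIE
#' @export
pairState <- function(x_i, x_j) {
  if (any(!is.finite(x_i)) || any(!is.finite(x_j)))
    stop("pairState requires finite inputs")
  ifelse(x_i > x_j, "GREATER", ifelse(x_i < x_j, "LESS", "TIE"))
}

#' Mine stable gene pairs within one class
#'
#' A directed pair (i, j) is stable when \code{x_i > x_j} (strictly) in at
#' least \code{threshold} of the class's samples; the threshold comparison is
#' inclusive. Ties count toward neither orientation. Since threshold > 0.5,
#' at most one orientation of a pair can qualify. Complexity is
#' O(G^2 * n) in genes G and samples n.
#'
#' @param mat numeric gene-by-sample matrix with rownames and colnames.
#' @param samples sample ids defining the class subset (default: all columns).
#' @param threshold stability fraction in (0.5, 1]; default 0.85.
#' @param classLabel optional class tag recorded in the result.
#' @param geneSubset optional gene ids to restrict mining to (pre-filter for
#'   tractability; the default pipeline filters after reversal detection).
#' @return a \linkS4class{GenePairSet} of type \code{"stable"}.
#' @export
mineStablePairs <- function(mat, samples = colnames(mat), threshold = 0.85,
                            classLabel = NA_character_, geneSubset = NULL) {
  if (length(samples) == 0L) stop("sample subset is empty")
  unknown <- setdiff(samples, colnames(mat))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (length(samples) < 2L) stop("need at least 2 samples to mine stable pairs")
  if (threshold <= 0.5 || threshold > 1) stop("threshold must lie in (0.5, 1]")
  X <- mat[, samples, drop = FALSE]
  if (!is.null(geneSubset)) {
    X <- X[rownames(X) %in% geneSubset, , drop = FALSE]
    if (nrow(X) < 2L) stop("fewer than 2 genes left after geneSubset restriction")
  }
  genes <- rownames(X)
  G <- nrow(X); n <- ncol(X)
  # C[i, j] = number of samples with x_i strictly greater than x_j
  C <- matrix(0L, G, G)
  for (s in seq_len(n)) {
    x <- X[, s]
    C <- C + outer(x, x, ">")
  }
  hit <- which(C >= threshold * n, arr.ind = TRUE)
  hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
  pairs <- data.frame(gene_i = genes[hit[, 1L]], gene_j = genes[hit[, 2L]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_i, pairs$gene_j), , drop = FALSE]
  GenePairSet(pairs, type = "stable", classLabel = classLabel,
              threshold = threshold)
}

#' Detect reversal pairs between two classes
#'
#' A pair (i, j) is a reversal pair when it is stable as \code{i > j} in the
#' case class and stable as \code{j > i} in the control class. The result
#' keeps the case orientation (gene_i higher in cases).
#'
#' @param stableCase stable \linkS4class{GenePairSet} mined in the case class.
#' @param stableControl stable \linkS4class{GenePairSet} mined in the control
#'   class.
#' @return a \linkS4class{GenePairSet} of type \code{"reversal"}.
#' @export
findReversalPairs <- function(stableCase, stableControl) {
  stopifnot(is(stableCase, "GenePairSet"), is(stableControl, "GenePairSet"))
  pc <- genePairs(stableCase)
  pk <- genePairs(stableControl)
  caseIds <- .pairId(pc$gene_i, pc$gene_j)
  controlFlipped <- .pairId(pk$gene_j, pk$gene_i)
  keep <- caseIds %in% controlFlipped
  pairs <- pc[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$gene_i, pairs$gene_j), , drop = FALSE]
  GenePairSet(pairs, type = "reversal",
              threshold = c(case = unname(stableCase@threshold[1]),
                            control = unname(stableControl@threshold[1])))
}

#' Filter a pair set by a gene whitelist
#'
#' Keeps a pair only when both genes are in the whitelist (e.g. secreted
#' genes, so the signature stays measurable in blood).
#'
#' @param pairSet a \linkS4class{GenePairSet}.
#' @param whitelist character vector of gene symbols.
#' @param caseInsensitive fold both sides to upper case before matching.
#' @return the filtered \linkS4class{GenePairSet}.
#' @export
filterPairsByGeneSet <- function(pairSet, whitelist, caseInsensitive = FALSE) {
  p <- genePairs(pairSet)
  gi <- p$gene_i; gj <- p$gene_j; wl <- whitelist
  if (caseInsensitive) { gi <- toupper(gi); gj <- toupper(gj); wl <- toupper(wl) }
  keep <- gi %in% wl & gj %in% wl
  out <- pairSet
  out@pairs <- p[keep, , drop = FALSE]
  rownames(out@pairs) <- NULL
  validObject(out)
  out
}

#' Encode samples into ternary pair space
#'
#' For each pair (gene_i, gene_j) and sample: code 0 when
#' \code{gene_i > gene_j}, 1 when \code{gene_i < gene_j}, and -1 otherwise
#' (exact tie, or either gene absent from the matrix, in which case the whole
#' pair row is -1). Each sample is encoded independently of all others.
#'
#' @param mat numeric gene-by-sample matrix.
#' @param pairs a \linkS4class{GenePairSet}, \linkS4class{GenePairSignature},
#'   or data.frame with columns \code{gene_i}, \code{gene_j}.
#' @return an \linkS4class{EncodedMatrix} (pairs x samples).
#' @export
encodeProfiles <- function(mat, pairs) {
  p <- if (is.data.frame(pairs)) pairs else genePairs(pairs)
  p <- data.frame(gene_i = as.character(p$gene_i),
                  gene_j = as.character(p$gene_j), stringsAsFactors = FALSE)
  if (nrow(p) == 0L) stop("no pairs to encode")
  nS <- ncol(mat)
  cd <- matrix(-1L, nrow(p), nS)
  present <- p$gene_i %in% rownames(mat) & p$gene_j %in% rownames(mat)
  for (r in which(present)) {
    xi <- mat[p$gene_i[r], ]
    xj <- mat[p$gene_j[r], ]
    cd[r, ] <- ifelse(xi > xj, 0L, ifelse(xi < xj, 1L, -1L))
  }
  em <- EncodedMatrix(cd, p)
  colnames(em) <- colnames(mat)
  em
}
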