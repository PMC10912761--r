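#' @include AllClasses.R
NULL

# plug-in discrete MI in nats over two categorical vectors; no validation
.miDiscrete <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  e <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Mutual information between a ternary feature and a binary class
#'
#' Plug-in estimator \eqn{\sum_{f,t} p(f,t)\,\ln[p(f,t)/(p(f)p(t))]} with the
#' convention \eqn{0 \ln 0 = 0}, in nats. The ternary codes \code{{-1,0,1}}
#' are treated as three categorical levels.
#'
#' @param f ternary code vector (values in \code{{-1, 0, 1}}).
#' @param t class vector with at most two distinct values.
#' @return non-negative numeric, in nats.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c("case", "case", "control", "control"))
#' # = log(2)
#' @export
mutualInformation <- function(f, t) {
  if (length(f) != length(t)) stop("length mismatch between f and t")
  if (length(f) < 1L) stop("empty vectors")
  if (!all(f %in% c(-1, 0, 1))) stop("f must take values in {-1, 0, 1}")
  if (length(unique(t)) > 2L) stop("t must be binary")
  .miDiscrete(f, t)
}

#' Rank pair-features by greedy mRMR
#'
#' Minimum-redundancy maximum-relevance ranking on the ternary codes. The
#' first feature maximizes MI with the class; each subsequent pick maximizes
#' \eqn{MI(f, T) - \frac{1}{|S|}\sum_{s \in S} MI(f, f_s)} over the remaining
#' features, where S is the already-selected set (standard greedy
#' difference-form mRMR). Ties break lexicographically by pair id.
#'
#' @param encoded an \linkS4class{EncodedMatrix}.
#' @param labels named \code{case}/\code{control} vector covering the encoded
#'   samples.
#' @param k number of features to rank (default: all).
#' @return a \linkS4class{RankedGenePairs} with method \code{"mRMR"}; the
#'   recorded score is the greedy criterion value at selection (plain
#'   relevance for the first feature).
#' @export
mrmrRank <- function(encoded, labels, k = nrow(encoded)) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(encoded))
  labs <- .canonLabels(labels)
  labs <- labs[colnames(encoded)]
  if (any(is.na(labs))) stop("labels missing for some encoded samples")
  if (length(unique(labs)) < 2L) stop("both classes must be present")
  cd <- codes(encoded)
  ids <- rownames(encoded)
  nF <- nrow(cd)
  rel <- vapply(seq_len(nF), function(i) .miDiscrete(cd[i, ], labs), 0)
  sel <- integer(0)
  score <- numeric(0)
  redSum <- numeric(nF)
  avail <- seq_len(nF)
  while (length(sel) < k) {
    if (length(sel) == 0L) {
      crit <- rel[avail]
    } else {
      last <- sel[length(sel)]
      redSum[avail] <- redSum[avail] +
        vapply(avail, function(i) .miDiscrete(cd[i, ], cd[last, ]), 0)
      crit <- rel[avail] - redSum[avail] / length(sel)
    }
    pick <- avail[order(-crit, ids[avail])[1L]]
    score <- c(score, crit[match(pick, avail)])
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  pr <- genePairs(encoded)[sel, , drop = FALSE]
  new("RankedGenePairs",
      ranking = data.frame(rank = seq_along(sel), pair_id = ids[sel],
                           gene_i = pr$gene_i, gene_j = pr$gene_j,
                           score = score, stringsAsFactors = FALSE),
      method = "mRMR")
}

#' Absolute Pearson correlation between a feature and the class
#'
#' Relevance term of MRMD: \eqn{|r|} between the code vector and the class
#' coded 0/1. Both reversal directions are informative, hence the absolute
#' value. A zero-variance input yields 0 with a warning.
#'
#' @param f numeric code vector.
#' @param t binary class vector (any two values, or 0/1 numerics).
#' @return numeric in [0, 1].
#' @export
pearsonRelevance <- function(f, t) {
  if (length(f) != length(t)) stop("length mismatch between f and t")
  if (length(f) < 2L) stop("need at least 2 observations")
  t01 <- if (is.numeric(t)) t else as.numeric(t == sort(unique(t))[1L])
  if (stats::sd(f) == 0 || stats::sd(t01) == 0) {
    warning("zero-variance input; relevance set to 0")
    return(0)
  }
  abs(stats::cor(f, t01))
}

#' Cosine distance between two feature vectors
#'
#' \eqn{1 - \frac{f_1 \cdot f_2}{\|f_1\|\|f_2\|}}, in [0, 2].
#'
#' @param f1,f2 numeric vectors of equal length; neither may be all-zero.
#' @return numeric in [0, 2].
#' @examples
#' cosineDistance(c(1, 0), c(0, 1))  # 1
#' @export
cosineDistance <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("length mismatch between f1 and f2")
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0) stop("f1 is a zero vector; cosine distance undefined")
  if (n2 == 0) stop("f2 is a zero vector; cosine distance undefined")
  1 - sum(f1 * f2) / (n1 * n2)
}

#' Rank pair-features by MRMD (relevance + mean cosine distance)
#'
#' Max-relevance max-distance ranking: each feature scores
#' \eqn{|r(f_i, T)| + \overline{d}_i}, where \eqn{\overline{d}_i} is the mean
#' cosine distance from \eqn{f_i} to every other candidate feature (larger
#' distance = lower redundancy), with equal unit weights on the two terms.
#' Features are ranked by descending score; ties break lexicographically by
#' pair id. With a single feature the distance term is 0. Inside the ranking,
#' a zero-norm feature's distance to anything is taken as 1 (neutral) so the
#' ranking never aborts on an uninformative all-zero row.
#'
#' @inheritParams mrmrRank
#' @return a \linkS4class{RankedGenePairs} with method \code{"MRMD"}.
#' @export
mrmdRank <- function(encoded, labels, k = nrow(encoded)) {
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(encoded))
  labs <- .canonLabels(labels)
  labs <- labs[colnames(encoded)]
  if (any(is.na(labs))) stop("labels missing for some encoded samples")
  if (length(unique(labs)) < 2L) stop("both classes must be present")
  cd <- codes(encoded)
  ids <- rownames(encoded)
  nF <- nrow(cd)
  t01 <- as.numeric(labs == "case")
  zeroVar <- apply(cd, 1L, stats::sd) == 0
  if (any(zeroVar))
    warning(sum(zeroVar), " zero-variance feature(s); relevance set to 0")
  rel <- numeric(nF)
  rel[!zeroVar] <- abs(apply(cd[!zeroVar, , drop = FALSE], 1L, stats::cor, y = t01))
  if (nF > 1L) {
    norms <- sqrt(rowSums(cd^2))
    sim <- (cd %*% t(cd)) / outer(norms, norms)
    sim[!is.finite(sim)] <- 0   # zero-norm rows: neutral distance 1
    D <- 1 - sim
    diag(D) <- NA
    meanDist <- rowMeans(D, na.rm = TRUE)
  } else {
    meanDist <- 0
  }
  score <- rel + meanDist
  ord <- order(-score, ids)[seq_len(k)]
  pr <- genePairs(encoded)[ord, , drop = FALSE]
  new("RankedGenePairs",
      ranking = data.frame(rank = seq_len(k), pair_id = ids[ord],
                           gene_i = pr$gene_i, gene_j = pr$gene_j,
                           score = score[ord], stringsAsFactors = FALSE),
      method = "MRMD")
}
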