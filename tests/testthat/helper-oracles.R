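# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct formula evaluation) so they are
# independent of the package's vectorized implementations.

# all directed stable pairs by a double loop over ordered gene pairs
bruteStablePairs <- function(mat, samples, threshold) {
  X <- mat[, samples, drop = FALSE]
  genes <- rownames(X)
  n <- ncol(X)
  out <- data.frame(gene_i = character(0), gene_j = character(0))
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      cnt <- 0L
      for (s in seq_len(n)) if (X[i, s] > X[j, s]) cnt <- cnt + 1L
      if (cnt / n >= threshold)
        out <- rbind(out, data.frame(gene_i = genes[i], gene_j = genes[j]))
    }
  }
  out[order(out$gene_i, out$gene_j), , drop = FALSE]
}

# reversal pairs by direct set intersection of flipped orientations
bruteReversalPairs <- function(stableCaseDf, stableControlDf) {
  keep <- logical(nrow(stableCaseDf))
  for (r in seq_len(nrow(stableCaseDf))) {
    keep[r] <- any(stableControlDf$gene_i == stableCaseDf$gene_j[r] &
                   stableControlDf$gene_j == stableCaseDf$gene_i[r])
  }
  stableCaseDf[keep, , drop = FALSE]
}

# plug-in MI from an explicitly assembled contingency table
bruteMI <- function(f, t) {
  lf <- sort(unique(f)); lt <- sort(unique(t))
  n <- length(f)
  mi <- 0
  for (a in lf) {
    for (b in lt) {
      pab <- sum(f == a & t == b) / n
      if (pab > 0) {
        pa <- sum(f == a) / n
        pb <- sum(t == b) / n
        mi <- mi + pab * log(pab / (pa * pb))
      }
    }
  }
  mi
}

# AUC as the pairwise Mann-Whitney count with half credit for ties
bruteAUC <- function(scores, truth) {
  sc <- scores[truth == "case"]
  sn <- scores[truth == "control"]
  tot <- 0
  for (a in sc) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sc) * length(sn))
}

# set-level mRMR criterion: mean relevance minus mean pairwise redundancy
# over every entry of the selected set crossed with itself
mrmrSetCriterion <- function(cd, labs, subset) {
  k <- length(subset)
  rel <- mean(vapply(subset, function(i) bruteMI(cd[i, ], labs), 0))
  red <- 0
  for (i in subset) for (j in subset) red <- red + bruteMI(cd[i, ], cd[j, ])
  rel - red / k^2
}

# random expression matrix with distinct values (no accidental ties)
randomMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  matrix(sample(seq_len(nGenes * nSamples * 10), nGenes * nSamples),
         nGenes, nSamples,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# labels helper
makeLabels <- function(nCase, nControl) {
  setNames(rep(c("case", "control"), c(nCase, nControl)),
           c(sprintf("CASE_%03d", seq_len(nCase)),
             sprintf("CTRL_%03d", seq_len(nControl))))
}

# EncodedMatrix straight from a code matrix with auto-named pairs
encodedFromCodes <- function(cd, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- sprintf("s%02d", seq_len(ncol(cd)))
  pairs <- data.frame(gene_i = sprintf("A%02d", seq_len(nrow(cd))),
                      gene_j = sprintf("B%02d", seq_len(nrow(cd))))
  em <- EncodedMatrix(cd, pairs)
  colnames(em) <- sampleIds
  em
}
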