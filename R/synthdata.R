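#' @include utils.R
NULL

#' Simulate two-class cohorts with planted reversal gene pairs
#'
#' Generates a gene-by-sample expression matrix in which background genes are
#' drawn iid log-normal per sample (no systematic ordering between any two of
#' them), and each planted pair carries a controlled ordering signal: in a
#' case sample \code{gene_i > gene_j} with probability
#' \code{stabilityCase}, in a control sample \code{gene_i < gene_j} with
#' probability \code{stabilityControl}. The two pair genes share a common
#' log-normal base level and are separated by a strictly positive
#' multiplicative offset whose direction is a per-sample Bernoulli draw, so
#' the expected concordance fraction is controlled exactly and orderings are
#' strict almost surely. The offset is kept small relative to between-gene
#' variability (mean 0.2 on the log scale against sdlog 1) so that genes of
#' different planted pairs do not order systematically against one another:
#' the planted pairs are the only systematic reversal signal, and cross-pair
#' or background orderings stay near chance. The log-normal marginals
#' (meanlog 5, sdlog 1) are otherwise arbitrary: every downstream result
#' depends only on within-sample orderings.
#'
#' @param nBackgroundGenes number of background (unordered) genes.
#' @param nPlantedPairs number of planted reversal pairs; their genes are
#'   disjoint from the background genes.
#' @param nCase,nControl cohort sizes.
#' @param stabilityCase,stabilityControl ordering stability in (0.5, 1].
#' @param noiseSd standard deviation of the log-offset magnitude (> 0);
#'   kept well below the mean offset so the offset stays positive.
#' @param meanlog,sdlog background log-normal parameters.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list with \code{matrix} (genes x samples), \code{labels} (named
#'   \code{case}/\code{control} vector), and \code{truth}: a data.frame of
#'   the planted pairs with realized per-class ordering fractions
#'   (\code{frac_case} of case samples with gene_i > gene_j,
#'   \code{frac_control} of control samples with gene_i < gene_j).
#' @examples
#' sim <- simulateCohorts(nBackgroundGenes = 20, nPlantedPairs = 2,
#'                        nCase = 10, nControl = 8, seed = 1)
#' sim$truth
#' @export
simulateCohorts <- function(nBackgroundGenes = 200, nPlantedPairs = 11,
                            nCase = 100, nControl = 50,
                            stabilityCase = 0.95, stabilityControl = 0.95,
                            noiseSd = 0.05, meanlog = 5, sdlog = 1,
                            seed = 20240304) {
  if (nBackgroundGenes < 1 || nPlantedPairs < 1 || nCase < 1 || nControl < 1)
    stop("all counts must be >= 1")
  for (s in c(stabilityCase, stabilityControl))
    if (s <= 0.5 || s > 1) stop("stability parameters must lie in (0.5, 1]")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  nS <- nCase + nControl
  sampleIds <- c(sprintf("CASE_%03d", seq_len(nCase)),
                 sprintf("CTRL_%03d", seq_len(nControl)))
  labels <- setNames(rep(c("case", "control"), c(nCase, nControl)), sampleIds)
  bgGenes <- sprintf("BG%04d", seq_len(nBackgroundGenes))
  giNames <- sprintf("SIGi%02d", seq_len(nPlantedPairs))
  gjNames <- sprintf("SIGj%02d", seq_len(nPlantedPairs))
  .withSeed(seed, {
    bg <- matrix(stats::rlnorm(nBackgroundGenes * nS, meanlog, sdlog),
                 nBackgroundGenes, nS, dimnames = list(bgGenes, sampleIds))
    planted <- matrix(0, 2L * nPlantedPairs, nS,
                      dimnames = list(c(rbind(giNames, gjNames)), sampleIds))
    isCase <- labels == "case"
    fracCase <- numeric(nPlantedPairs)
    fracControl <- numeric(nPlantedPairs)
    for (p in seq_len(nPlantedPairs)) {
      base <- stats::rlnorm(nS, meanlog, sdlog)
      sep <- abs(stats::rnorm(nS, mean = 0.2, sd = noiseSd)) + 1e-6
      hi <- base * exp(sep / 2)
      lo <- base * exp(-sep / 2)
      # concordant = gene_i on the high side (the case pattern)
      concordant <- logical(nS)
      concordant[isCase] <- stats::rbinom(nCase, 1L, stabilityCase) == 1L
      concordant[!isCase] <- stats::rbinom(nControl, 1L, 1 - stabilityControl) == 1L
      xi <- ifelse(concordant, hi, lo)
      xj <- ifelse(concordant, lo, hi)
      planted[2L * p - 1L, ] <- xi
      planted[2L * p, ] <- xj
      fracCase[p] <- mean(xi[isCase] > xj[isCase])
      fracControl[p] <- mean(xi[!isCase] < xj[!isCase])
    }
    truth <- data.frame(gene_i = giNames, gene_j = gjNames,
                        frac_case = fracCase, frac_control = fracControl,
                        stringsAsFactors = FALSE)
    list(matrix = rbind(planted, bg), labels = labels, truth = truth)
  })
}

#' Apply a strictly increasing per-sample transform
#'
#' Test harness for the REO invariance property: stable pairs, encodings and
#' predictions must be bit-identical before and after any of these
#' transforms, because each is strictly increasing within every sample.
#'
#' @param mat numeric gene-by-sample matrix.
#' @param kind \code{"log2"} (requires positive values),
#'   \code{"affine_positive"} (slope * x + intercept, slope > 0), or
#'   \code{"rank"} (within-sample ranks, average ties).
#' @param slope,intercept parameters of the affine transform.
#' @return transformed matrix of the same shape.
#' @export
monotoneTransform <- function(mat, kind = c("log2", "affine_positive", "rank"),
                              slope = 2, intercept = 5) {
  kind <- match.arg(kind)
  switch(kind,
    log2 = {
      if (any(mat <= 0)) stop("log2 transform requires positive values")
      log2(mat)
    },
    affine_positive = {
      if (slope <= 0) stop("slope must be positive")
      slope * mat + intercept
    },
    rank = apply(mat, 2L, rank, ties.method = "average"))
}
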