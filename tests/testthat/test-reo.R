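test_that("pairState performs strict comparisons with TIE on equality", {
  expect_identical(pairState(5, 3), "GREATER")
  expect_identical(pairState(1, 2), "LESS")
  expect_identical(pairState(3, 3), "TIE")
  expect_error(pairState(NA_real_, 1), "finite")
  expect_error(pairState(Inf, 1), "finite")
})

test_that("unanimous orderings are mined and the threshold is inclusive", {
  m <- matrix(c(4, 1, 5, 2, 6, 3, 7, 1), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  sp <- mineStablePairs(m, threshold = 0.85)
  expect_identical(genePairs(sp),
                   data.frame(gene_i = "g1", gene_j = "g2"))

  # g1 > g2 in exactly 17/20 samples = 0.85: inclusive >= keeps the pair
  m2 <- rbind(g1 = c(rep(2, 17), rep(0, 3)), g2 = rep(1, 20))
  colnames(m2) <- paste0("s", 1:20)
  expect_identical(genePairs(mineStablePairs(m2, threshold = 0.85)),
                   data.frame(gene_i = "g1", gene_j = "g2"))
  # and 16/20 < 0.85 drops it
  m3 <- rbind(g1 = c(rep(2, 16), rep(0, 4)), g2 = rep(1, 20))
  colnames(m3) <- paste0("s", 1:20)
  expect_identical(nrow(genePairs(mineStablePairs(m3, threshold = 0.85))), 0L)
})

test_that("mining validates its inputs", {
  m <- randomMatrix(3, 4, seed = 1)
  expect_error(mineStablePairs(m, samples = character(0)), "empty")
  expect_error(mineStablePairs(m, samples = c("s01", "zz")), "unknown sample")
  expect_error(mineStablePairs(m, samples = "s01"), "at least 2")
  expect_error(mineStablePairs(m, threshold = 0.5), "0.5, 1")
})

test_that("mining matches the brute-force double loop on random matrices", {
  for (seed in 1:12) {
    nG <- sample(3:8, 1)
    nS <- sample(4:12, 1)
    m <- randomMatrix(nG, nS, seed = seed)
    thr <- sample(c(0.6, 0.75, 0.85, 1.0), 1)
    got <- genePairs(mineStablePairs(m, threshold = thr))
    want <- bruteStablePairs(m, colnames(m), thr)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("reversal detection keeps case orientation and drops concordance", {
  sc <- GenePairSet(data.frame(gene_i = "a", gene_j = "b"), classLabel = "case")
  stRev <- GenePairSet(data.frame(gene_i = "b", gene_j = "a"),
                       classLabel = "control")
  stConc <- GenePairSet(data.frame(gene_i = "a", gene_j = "b"),
                        classLabel = "control")
  expect_identical(genePairs(findReversalPairs(sc, stRev)),
                   data.frame(gene_i = "a", gene_j = "b"))
  expect_identical(nrow(genePairs(findReversalPairs(sc, stConc))), 0L)
})

test_that("reversal detection matches brute force on random cohorts", {
  for (seed in 1:10) {
    m <- randomMatrix(6, 10, seed = 100 + seed)
    caseIds <- colnames(m)[1:5]
    ctrlIds <- colnames(m)[6:10]
    sc <- mineStablePairs(m, caseIds, 0.6, "case")
    st <- mineStablePairs(m, ctrlIds, 0.6, "control")
    got <- genePairs(findReversalPairs(sc, st))
    want <- bruteReversalPairs(bruteStablePairs(m, caseIds, 0.6),
                               bruteStablePairs(m, ctrlIds, 0.6))
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("whitelist filtering keeps a pair only when both genes are listed", {
  rev <- GenePairSet(data.frame(gene_i = c("a", "a"), gene_j = c("b", "c")),
                     type = "reversal",
                     threshold = c(case = 0.85, control = 0.85))
  expect_identical(genePairs(filterPairsByGeneSet(rev, c("a", "b"))),
                   data.frame(gene_i = "a", gene_j = "b"))
  expect_identical(genePairs(filterPairsByGeneSet(rev, c("a", "b", "c"))),
                   genePairs(rev))
  expect_identical(nrow(genePairs(filterPairsByGeneSet(rev, character(0)))), 0L)
})

test_that("encoding maps orderings to 0/1 and everything else to -1", {
  m <- matrix(c(2, 1, 1, 2, 3, 3), 2, 3,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  enc <- encodeProfiles(m, data.frame(gene_i = "a", gene_j = "b"))
  expect_identical(as.vector(codes(enc)), c(0L, 1L, -1L))

  # absent gene: whole pair row is -1
  enc2 <- encodeProfiles(m, data.frame(gene_i = c("a", "a"),
                                       gene_j = c("b", "z")))
  expect_identical(as.vector(codes(enc2)["a|z", ]), rep(-1L, 3))
  expect_error(encodeProfiles(m, data.frame(gene_i = character(0),
                                            gene_j = character(0))),
               "no pairs")
})

test_that("per-pair code fractions always sum to one", {
  sim <- simulateCohorts(nBackgroundGenes = 10, nPlantedPairs = 3,
                         nCase = 15, nControl = 10, seed = 5)
  enc <- encodeProfiles(sim$matrix, sim$truth[, c("gene_i", "gene_j")])
  cd <- codes(enc)
  fr <- rowMeans(cd == 0L) + rowMeans(cd == 1L) + rowMeans(cd == -1L)
  expect_equal(unname(fr), rep(1, nrow(cd)))
})

test_that("REO outputs are bit-identical under monotone per-sample transforms", {
  for (seed in 1:5) {
    sim <- simulateCohorts(nBackgroundGenes = 15, nPlantedPairs = 2,
                           nCase = 12, nControl = 10,
                           stabilityCase = 0.9, stabilityControl = 0.9,
                           seed = 200 + seed)
    m <- sim$matrix
    labs <- sim$labels
    caseIds <- names(labs)[labs == "case"]
    base <- genePairs(mineStablePairs(m, caseIds, 0.85))
    enc <- codes(encodeProfiles(m, sim$truth[, c("gene_i", "gene_j")]))
    for (kind in c("log2", "affine_positive", "rank")) {
      mt <- monotoneTransform(m, kind)
      expect_identical(genePairs(mineStablePairs(mt, caseIds, 0.85)), base)
      expect_identical(codes(encodeProfiles(mt, sim$truth[, c("gene_i", "gene_j")])),
                       enc)
    }
  }
})

test_that("stable pairs at threshold 1 are a subset of any lower threshold", {
  for (seed in 1:5) {
    m <- randomMatrix(6, 8, seed = 300 + seed)
    hi <- pairIds(mineStablePairs(m, threshold = 1.0))
    for (thr in c(0.6, 0.75, 0.85)) {
      lo <- pairIds(mineStablePairs(m, threshold = thr))
      expect_true(all(hi %in% lo))
    }
  }
})

test_that("at most one orientation of a pair can be stable", {
  for (seed in 1:5) {
    m <- randomMatrix(7, 9, seed = 400 + seed)
    p <- genePairs(mineStablePairs(m, threshold = 0.6))
    if (nrow(p)) {
      unord <- paste(pmin(p$gene_i, p$gene_j), pmax(p$gene_i, p$gene_j))
      expect_identical(anyDuplicated(unord), 0L)
    }
  }
})

test_that("planted pairs at stability 1.0 are recovered exactly", {
  sim <- simulateCohorts(nBackgroundGenes = 30, nPlantedPairs = 5,
                         nCase = 20, nControl = 15,
                         stabilityCase = 1.0, stabilityControl = 1.0,
                         seed = 9)
  labs <- sim$labels
  sc <- mineStablePairs(sim$matrix, names(labs)[labs == "case"], 0.85)
  st <- mineStablePairs(sim$matrix, names(labs)[labs == "control"], 0.85)
  rev <- findReversalPairs(sc, st)
  planted <- paste(sim$truth$gene_i, sim$truth$gene_j, sep = "|")
  expect_setequal(pairIds(rev), planted)
})
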