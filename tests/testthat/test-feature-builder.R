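seFrom <- function(counts, rin = rep(8, ncol(counts)),
                   group = rep("g1", ncol(counts))) {
  expressionSE(counts, rin = rin, group = group)
}

test_that("sample filtering applies inclusive RIN and group-size rules", {
  counts <- matrix(10L, nrow = 3, ncol = 31,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:31)))
  # all rin = 7, group size 31 -> unchanged
  se <- seFrom(counts, rin = rep(7, 31))
  expect_identical(colnames(filterSamples(se)), colnames(se))
  # rin exactly 6.0 -> removed (boundary inclusive); group still >= 30
  rin <- rep(7, 31); rin[5] <- 6.0
  se <- seFrom(counts, rin = rin)
  kept <- colnames(filterSamples(se))
  expect_false("s5" %in% kept)
  expect_length(kept, 30)
  # RIN filter drops the group to 29 -> whole group removed, with warning
  rin <- rep(7, 31); rin[1:2] <- 5
  se <- seFrom(counts, rin = rin)
  expect_warning(out <- filterSamples(se), "all samples removed")
  expect_identical(ncol(out), 0L)
})

test_that("PCA outlier flagging finds exactly the displaced sample", {
  counts <- outlierCounts(nS = 50, nG = 20)
  se <- seFrom(counts)
  flagged <- flagOutliersPCA(se)
  expect_identical(flagged, "S50")
  # oracle: eigen-decomposition of the gene-gene covariance on log2 cpm,
  # samples projected onto the dominant eigenvector
  x <- log2(edgeR::cpm(counts) + 1)
  xc <- x - rowMeans(x)
  ev <- eigen(xc %*% t(xc) / (ncol(xc) - 1), symmetric = TRUE)
  sc <- t(xc) %*% ev$vectors[, 1]
  expect_identical(colnames(counts)[which.max(abs(sc))], "S50")
  # identical samples -> zero variance -> nothing flagged
  se0 <- seFrom(matrix(5L, 4, 10, dimnames = list(paste0("g", 1:4),
                                                  paste0("s", 1:10))))
  expect_identical(flagOutliersPCA(se0), character(0))
  # lowering the threshold can only grow the flagged set
  expect_true(all(flagged %in% flagOutliersPCA(se, zCut = 0.5)))
  expect_error(flagOutliersPCA(se[, 1:2]), "at least 3")
})

test_that("cpm normalisation and Spearman correlations behave", {
  # column with counts (1,1,2) sums to 4 -> cpm (250000, 250000, 500000)
  counts <- matrix(c(1L, 1L, 2L,
                     2L, 3L, 5L,
                     1L, 1L, 1L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  cpm <- edgeR::cpm(counts)
  expect_equal(unname(cpm[, 1]), c(250000, 250000, 500000))
  expect_equal(unname(colSums(cpm)), rep(1e6, 3), tolerance = 1e-6)
  # identical count vectors correlate at 1; cpm-reversed ranks at -1
  counts2 <- matrix(c(1L, 3L, 1L,
                      2L, 2L, 2L,
                      3L, 1L, 3L), nrow = 3, byrow = FALSE,
                    dimnames = list(c("gA", "gB", "gD"), c("s1", "s2", "s3")))
  counts2["gA", ] <- c(1L, 2L, 3L)
  counts2["gB", ] <- c(3L, 2L, 1L)
  counts2["gD", ] <- c(1L, 2L, 3L)
  cc2 <- coexpressionMatrix(seFrom(counts2))
  expect_equal(cc2["gA", "gD"], 1)
  expect_equal(cc2["gA", "gB"], -1)
  expect_true(isSymmetric(cc2))
  expect_equal(unname(diag(cc2)), rep(1, 3))
  # a constant gene (constant after cpm: equal library sizes) -> NA, not 0
  counts3 <- matrix(c(1L, 2L, 3L,
                      3L, 3L, 3L,
                      2L, 1L, 0L), nrow = 3, byrow = TRUE,
                    dimnames = list(c("g1", "g5", "g6"), c("s1", "s2", "s3")))
  cc3 <- coexpressionMatrix(seFrom(counts3))
  expect_true(is.na(cc3["g1", "g5"]))
  # Spearman is invariant to a strictly monotone transform of the
  # normalised values
  withSeedCounts <- matrix(rpois(200, 50), nrow = 10,
                           dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  seA <- seFrom(withSeedCounts)
  ccA <- coexpressionMatrix(seA)
  cpmA <- edgeR::cpm(withSeedCounts)
  ccB <- suppressWarnings(stats::cor(t(log2(cpmA + 1)), method = "spearman"))
  diag(ccB) <- 1
  expect_equal(ccA, ccB, tolerance = 1e-12)
})

test_that("top-percentile pair selection sizes and tie-breaks are exact", {
  set.seed(1)
  g <- sprintf("g%02d", 1:40)               # 780 off-diagonal pairs
  x <- matrix(rnorm(40 * 60), nrow = 40, dimnames = list(g, NULL))
  cc <- cor(t(x))
  ch <- topPercentilePairs(cc, 0.1)
  expect_length(channelPairs(ch), 1)        # ceil(0.001 * 780) = 1
  # brute-force oracle: the single highest off-diagonal value
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  best <- which.max(cc[ut])
  expect_identical(channelPairs(ch),
                   pairKey(g[ut[best, 1]], g[ut[best, 2]]))
  ch10 <- topPercentilePairs(cc, 1)         # ceil(7.8) = 8 largest
  expect_length(channelPairs(ch10), 8)
  ord <- order(-cc[ut])
  expect_setequal(channelPairs(ch10),
                  pairKey(g[ut[ord[1:8], 1]], g[ut[ord[1:8], 2]]))
  # all values tied -> first ceil(p) pairs in canonical pair order
  ccT <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(ccT) <- 1
  chT <- topPercentilePairs(ccT, 50)        # ceil(3) = 3 of 6 pairs
  expect_identical(channelPairs(chT), c("a|b", "a|c", "a|d"))
})

test_that("ortholog mapping expands, drops self-pairs and reports drops", {
  ch <- featureChannel("yeast", "ppi", c("Y1|Y2"))
  out <- mapPairsViaOrthologs(ch, list(Y1 = "A", Y2 = "B"))
  expect_identical(channelPairs(out), "A|B")
  # self-pairs from shared orthologs are dropped
  out2 <- mapPairsViaOrthologs(ch, list(Y1 = c("A", "B"), Y2 = "A"))
  expect_identical(channelPairs(out2), "A|B")
  # unmapped member drops the pair and is counted
  out3 <- mapPairsViaOrthologs(ch, list(Y1 = "A"))
  expect_length(channelPairs(out3), 0)
  expect_identical(out3@meta$droppedPairs, 1L)
  # identity map is idempotent
  hch <- featureChannel("h", "ppi", c("A|B", "C|D"))
  idm <- list(A = "A", B = "B", C = "C", D = "D")
  expect_identical(channelPairs(mapPairsViaOrthologs(hch, idm)),
                   channelPairs(hch))
})

test_that("odds ratios match exhaustive 2x2 cross-tabulation", {
  uni <- allPairKeys(LETTERS[1:8])                    # 28 pairs
  fis <- uni[1:10]
  ch <- featureChannel("c", "ppi", c(uni[1:8], uni[11:12]))  # a=8 b=2 c=2 d=16
  rep1 <- pairwiseOddsRatio(ch, fis, uni)
  expect_identical(c(rep1$a, rep1$b, rep1$c, rep1$d), c(8L, 2L, 2L, 16L))
  expect_equal(rep1$odds_ratio, (8 * 16) / (2 * 2))
  # independence with equal margins: a=b=c=d -> OR 1
  uni2 <- allPairKeys(LETTERS[1:5])                   # 10 pairs; use 8
  fis2 <- uni2[1:4]
  ch2 <- featureChannel("c2", "ppi", uni2[c(1, 2, 5, 6)])  # a=2 b=2 c=2 d=2
  expect_equal(pairwiseOddsRatio(ch2, fis2, uni2[1:8])$odds_ratio, 1)
  # zero cell -> Haldane correction keeps it finite
  ch3 <- featureChannel("c3", "ppi", uni[1:3])        # b = 0
  rep3 <- pairwiseOddsRatio(ch3, fis, uni)
  expect_true(is.finite(rep3$odds_ratio))
  expect_equal(rep3$odds_ratio, (3.5 * 18.5) / (0.5 * 7.5))
  expect_error(pairwiseOddsRatio(ch, fis, character(0)), "empty")
  # property: random channels against a set-operation oracle
  set.seed(99)
  for (i in 1:20) {
    chR <- featureChannel("r", "ppi", sample(uni, sample(3:15, 1)))
    fiR <- sample(uni, sample(3:15, 1))
    rp <- pairwiseOddsRatio(chR, fiR, uni)
    a <- length(intersect(chR@pairs, fiR))
    b <- length(setdiff(chR@pairs, fiR))
    cc <- length(setdiff(fiR, chR@pairs))
    d <- 28L - a - b - cc
    expect_identical(c(rp$a, rp$b, rp$c, rp$d), c(a, b, cc, d))
    orExp <- if (min(a, b, cc, d) == 0)
      (a + .5) * (d + .5) / ((b + .5) * (cc + .5)) else a * d / (b * cc)
    expect_equal(rp$odds_ratio, orExp)
  }
})

test_that("feature vetting is strict at the threshold", {
  # construct OR exactly 5: a=5, b=2, c=7, d=14 over 28 pairs
  uni <- allPairKeys(LETTERS[1:8])
  fis <- uni[1:12]
  ch5 <- featureChannel("exact5", "ppi", c(uni[1:5], uni[13:14]))
  expect_equal(pairwiseOddsRatio(ch5, fis, uni)$odds_ratio, 5)
  sel <- selectFeatures(list(ch5), fis, uni, threshold = 5)
  expect_length(sel$selected, 0)            # strictly greater than 5 required
  ch16 <- featureChannel("strong", "ppi", c(uni[1:8], uni[13:14]))
  sel2 <- selectFeatures(list(ch5, ch16), fis, uni, threshold = 5)
  expect_identical(sel2$selected, "strong")
  expect_identical(nrow(sel2$reports), 2L)  # a report for every channel
  sel0 <- selectFeatures(list(), fis, uni)
  expect_length(sel0$selected, 0)
})

test_that("feature matrix assembly is binary, ordered and label-consistent", {
  chans <- list(featureChannel("c1", "ppi", c("A|B", "C|D")),
                featureChannel("c2", "gobp", c("A|B")),
                featureChannel("c3", "domain", c("E|F")))
  fm <- assembleFeatureMatrix(c("A|B", "C|D", "A|C"), chans)
  expect_identical(pairIndex(fm), c("A|B", "A|C", "C|D"))
  expect_identical(unname(featureValues(fm)["A|B", ]), c(1L, 1L, 0L))
  # column sums equal channel intersections with the pair index
  cs <- colSums(featureValues(fm))
  for (ch in chans) {
    expect_equal(unname(cs[ch@name]),
                 length(intersect(ch@pairs, pairIndex(fm))))
  }
  expect_identical(nrow(featureValues(assembleFeatureMatrix(character(0),
                                                            chans))), 0L)
  expect_error(assembleFeatureMatrix("A|B", chans[c(1, 1)]), "duplicate")
})
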