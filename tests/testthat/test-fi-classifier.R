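# a separable world: channel "signal" contains exactly the FI pairs,
# "noise" is random
separableWorld <- function(nGenes = 60, seed = 5) {
  genes <- sprintf("G%03d", seq_len(nGenes))
  uni <- allPairKeys(genes)
  set.seed(seed)
  fis <- sort(sample(uni, 80), method = "radix")
  chans <- list(
    featureChannel("signal", "gobp", fis),
    featureChannel("noise", "ppi", sample(uni, 120)))
  list(genes = genes, uni = uni, fis = fis, chans = chans)
}

test_that("training sets sample negatives reproducibly at the requested ratio", {
  genes <- sprintf("G%03d", 1:150)              # 11,175 pairs
  uni <- allPairKeys(genes)
  fis <- uni[seq(1, 2000, by = 20)]             # 100 positives
  ts <- buildTrainingSet(fis, genes, negRatio = 100, seed = 42)
  expect_length(ts@negatives, 10000)            # 100 positives : 10,000 negatives
  expect_length(intersect(ts@positives, ts@negatives), 0)
  expect_true(validObject(ts))
  ts2 <- buildTrainingSet(fis, genes, negRatio = 100, seed = 42)
  expect_identical(ts2@negatives, ts@negatives) # same seed, same sample
  ts3 <- buildTrainingSet(fis, genes, negRatio = 100, seed = 43)
  expect_false(identical(ts3@negatives, ts@negatives))
  # infeasible ratio errors and states the maximum attainable one
  expect_error(buildTrainingSet(fis, genes, negRatio = 200, seed = 1),
               "max attainable ratio: 110")
})

test_that("a separable channel yields perfect held-out performance", {
  w <- separableWorld()
  ts <- buildTrainingSet(w$fis, w$genes, w$chans, negRatio = 10, seed = 42)
  fit <- trainAndEvaluate(ts, classifierConfig(), repeats = 5)
  expect_equal(fit$report$auc, 1.0)
  expect_equal(fit$report$recall, 1.0)          # balanced weights recover positives
  expect_identical(nrow(fit$report$perFold), 5L)
  expect_true(all(fit$report$perFold$auc >= 0) &&
                all(fit$report$perFold$auc <= 1))
  # scores: member pairs ~1, all-zero-feature pairs ~0
  fm <- assembleFeatureMatrix(w$uni, w$chans)
  sc <- predictScores(fit$model, fm)
  inSig <- names(sc) %in% w$fis
  inNoise <- names(sc) %in% w$chans[[2]]@pairs
  expect_gt(min(sc[inSig]), 0.7)
  expect_lt(max(sc[!inSig & !inNoise]), 0.3)
  # monotone fixture property on averages
  expect_gt(mean(sc[inSig]), mean(sc[!inSig]))
  # the informative channel ranks first and importances are a distribution
  imp <- featureImportance(fit$model)
  expect_identical(imp$channel[1], "signal")
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
})

test_that("shuffled labels give chance-level AUC", {
  w <- separableWorld(nGenes = 40, seed = 9)
  ts <- buildTrainingSet(w$fis, w$genes, w$chans, negRatio = 5, seed = 42)
  fm <- ts@featureMatrix
  y <- fiLabels(fm)
  aucs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    ys <- sample(y)
    pos <- pairIndex(fm)[ys == 1]
    neg <- pairIndex(fm)[ys == 0]
    fm2 <- new("FeatureMatrix", pairIndex = pairIndex(fm),
               channels = channelNames(fm), values = fm@values, labels = ys)
    ts2 <- new("TrainingSet", featureMatrix = fm2, positives = sort(pos),
               negatives = sort(neg), seed = 1L)
    trainAndEvaluate(ts2, classifierConfig(nTrees = 100, randomState = i),
                     repeats = 1)$report$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("prediction enforces the channel contract and survives persistence", {
  w <- separableWorld()
  ts <- buildTrainingSet(w$fis, w$genes, w$chans, negRatio = 5, seed = 42)
  fit <- trainAndEvaluate(ts, classifierConfig(), repeats = 2)
  fm <- assembleFeatureMatrix(w$uni[1:50], w$chans)
  sc <- predictScores(fit$model, fm)
  expect_true(all(sc >= 0 & sc <= 1))
  # identical feature rows get identical scores
  v <- featureValues(fm)
  dup <- which(duplicated(v) | duplicated(v, fromLast = TRUE))
  key <- apply(v, 1, paste, collapse = "")
  for (k in unique(key[dup])) expect_length(unique(sc[key == k]), 1)
  # channel mismatch errors name the offender
  fmBad <- assembleFeatureMatrix(w$uni[1:10], w$chans[1])
  expect_error(predictScores(fit$model, fmBad), "noise")
  fmExtra <- assembleFeatureMatrix(
    w$uni[1:10], c(w$chans, list(featureChannel("rogue", "ppi", "A|B"))))
  expect_error(predictScores(fit$model, fmExtra), "rogue")
  # save/reload: no score drift
  f <- withr::local_tempfile(fileext = ".rds")
  saveFIClassifier(fit$model, f)
  m2 <- loadFIClassifier(f)
  expect_identical(predictScores(m2, fm), sc)
  saveRDS(list(format = "other"), f)
  expect_error(loadFIClassifier(f), "not a recognised")
})

test_that("single-class training sets are refused", {
  w <- separableWorld()
  fm <- assembleFeatureMatrix(w$fis, w$chans,
                              labels = rep(1L, length(w$fis)))
  ts <- new("TrainingSet", featureMatrix = fm, positives = w$fis,
            negatives = character(0), seed = 1L)
  expect_error(trainAndEvaluate(ts), "both classes")
})

test_that("score thresholding is inclusive at the cutoff", {
  sc <- c("A|B" = 0.80, "C|D" = 0.7999, "E|F" = 1.0, "G|H" = 0)
  expect_identical(thresholdPredictions(sc, 0.8), c("A|B", "E|F"))
  expect_identical(thresholdPredictions(numeric(0)), character(0))
  expect_error(thresholdPredictions(sc, 1.5))
})
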