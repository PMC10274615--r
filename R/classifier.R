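# FI classifier: training-set construction (reference FIs vs random pairs),
# random-forest training/evaluation, thresholded prediction and feature
# importances. The classifier contract is a probabilistic binary classifier
# with per-feature importances; the implementation is a probability random
# forest (ranger) with the published hyperparameters as defaults.

#' Classifier configuration
#'
#' Defaults follow the published random-forest settings: 200 trees, maximum
#' depth 10, balanced class weights, minimum leaf size 1, fixed random state
#' 42.
#'
#' @param nTrees Number of trees (n_estimators), default 200.
#' @param maxDepth Maximum tree depth, default 10.
#' @param classWeight `"balanced"` (inverse class-frequency case weights) or
#'   `"none"`.
#' @param minNodeSize Minimum leaf size (min_samples_leaf), default 1.
#' @param randomState Integer RNG seed for training, default 42.
#' @param mtry Features tried per split; `NULL` = ranger default (sqrt(p)).
#' @param ... Further ensemble knobs kept as a free-form list.
#' @return A classed list of settings.
#' @export
classifierConfig <- function(nTrees = 200L, maxDepth = 10L,
                             classWeight = c("balanced", "none"),
                             minNodeSize = 1L, randomState = 42L,
                             mtry = NULL, ...) {
  classWeight <- match.arg(classWeight)
  stopifnot(nTrees >= 1)
  cfg <- list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
              classWeight = classWeight, minNodeSize = as.integer(minNodeSize),
              randomState = as.integer(randomState), mtry = mtry,
              extra = list(...))
  class(cfg) <- "classifierConfig"
  cfg
}

#' Build a labelled training set from reference FIs and random pairs
#'
#' Positives are the reference FIs; negatives are sampled uniformly without
#' replacement from the non-FI canonical pairs over `geneUniverse` (known
#' positives are excluded, nothing else). Reproducible under `seed`.
#'
#' @param fis Character vector of reference-FI pair keys.
#' @param geneUniverse Character vector of gene symbols defining the pair
#'   universe.
#' @param channels List of [FeatureChannel-class] objects used to populate
#'   the feature matrix (may be empty).
#' @param negRatio Negatives per positive, default 100 (the published
#'   grid-search protocol used 100 positives : 10,000 negatives).
#' @param seed Integer seed for negative sampling.
#' @return A [TrainingSet-class]. Errors when the universe cannot supply the
#'   requested number of negatives, stating the maximum attainable ratio.
#' @export
buildTrainingSet <- function(fis, geneUniverse, channels = list(),
                             negRatio = 100L, seed = 42L) {
  stopifnot(negRatio >= 1, length(fis) >= 1)
  fis <- sort(unique(fis), method = "radix")
  universe <- allPairKeys(geneUniverse)
  if (length(setdiff(fis, universe)))
    stop("some FI pairs fall outside the gene universe")
  pool <- setdiff(universe, fis)
  need <- as.integer(negRatio) * length(fis)
  if (length(pool) < need) {
    stop(sprintf(
      "universe has only %d non-FI pairs; cannot sample %d negatives (max attainable ratio: %d)",
      length(pool), need, length(pool) %/% length(fis)))
  }
  negatives <- withSeed(seed, sort(sample(pool, need), method = "radix"))
  idx <- c(fis, negatives)
  labels <- c(rep(1L, length(fis)), rep(0L, length(negatives)))
  ord <- order(idx, method = "radix")
  fm <- assembleFeatureMatrix(idx[ord], channels, labels = labels[ord])
  new("TrainingSet", featureMatrix = fm, positives = fis,
      negatives = negatives, seed = as.integer(seed))
}

rangerData <- function(fm) {
  d <- as.data.frame(featureValues(fm))
  colnames(d) <- make.names(channelNames(fm))
  d
}

fitForest <- function(x, y, cfg, seed) {
  d <- cbind(x, .label = factor(y, levels = c("0", "1")))
  cw <- NULL
  if (cfg$classWeight == "balanced") {
    tab <- table(d$.label)
    w <- length(y) / (2 * tab)
    cw <- as.numeric(w[as.character(d$.label)])
  }
  ranger::ranger(
    dependent.variable.name = ".label", data = d,
    num.trees = cfg$nTrees, max.depth = cfg$maxDepth,
    min.node.size = cfg$minNodeSize,
    mtry = cfg$mtry,
    probability = TRUE, importance = "impurity",
    case.weights = cw,
    seed = seed, num.threads = 1, verbose = FALSE
  )
}

forestScores <- function(model, x) {
  # loading the namespace registers predict.ranger for models restored
  # from disk
  requireNamespace("ranger", quietly = TRUE)
  pr <- stats::predict(model, data = x, num.threads = 1, verbose = FALSE)
  pr$predictions[, "1"]
}

binaryMetrics <- function(truth, score, cutoff = 0.5) {
  pred <- as.integer(score >= cutoff)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  auc <- as.numeric(pROC::auc(
    response = factor(truth, levels = c(0, 1)), predictor = score,
    levels = c("0", "1"), direction = "<", quiet = TRUE))
  c(auc = auc, precision = precision, recall = recall, f1 = f1)
}

#' Train the FI classifier with repeated stratified hold-out evaluation
#'
#' Repeats `repeats` stratified random 75/25 (by default) splits, averaging
#' AUC, precision, recall and F1 over the held-out folds, then refits the
#' final model on all data.
#'
#' @param ts A [TrainingSet-class] with both classes present.
#' @param cfg A [classifierConfig()].
#' @param holdout Validation fraction per repeat, default 0.25.
#' @param repeats Number of random splits, default 10.
#' @return List with `model` (an [FIClassifier-class] refit on all data) and
#'   `report` (mean metrics plus a `perFold` data.frame).
#' @export
trainAndEvaluate <- function(ts, cfg = classifierConfig(), holdout = 0.25,
                             repeats = 10L) {
  fm <- ts@featureMatrix
  y <- fiLabels(fm)
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  x <- rangerData(fm)
  folds <- lapply(seq_len(repeats), function(r) {
    withSeed(cfg$randomState + r, {
      val <- unlist(lapply(split(seq_along(y), y), function(idx) {
        sample(idx, max(1L, floor(holdout * length(idx))))
      }), use.names = FALSE)
      m <- fitForest(x[-val, , drop = FALSE], y[-val], cfg,
                     seed = cfg$randomState + r)
      binaryMetrics(y[val], forestScores(m, x[val, , drop = FALSE]))
    })
  })
  perFold <- as.data.frame(do.call(rbind, folds))
  perFold$fold <- seq_len(repeats)
  report <- list(
    auc = mean(perFold$auc), precision = mean(perFold$precision, na.rm = TRUE),
    recall = mean(perFold$recall, na.rm = TRUE),
    f1 = mean(perFold$f1, na.rm = TRUE), perFold = perFold
  )
  final <- fitForest(x, y, cfg, seed = cfg$randomState)
  model <- new("FIClassifier", model = final, channels = channelNames(fm),
               config = unclass(cfg))
  list(model = model, report = report)
}

#' Predict FI scores for gene pairs
#'
#' @param model An [FIClassifier-class].
#' @param fm A [FeatureMatrix-class] whose channels match the model's
#'   training channels by name and order (otherwise an error names the
#'   missing/extra channels).
#' @return Named numeric vector: canonical pair key -> score in `[0,1]`
#'   (the FI score table).
#' @export
predictScores <- function(model, fm) {
  if (!identical(channelNames(fm), model@channels)) {
    missing <- setdiff(model@channels, channelNames(fm))
    extra <- setdiff(channelNames(fm), model@channels)
    stop("feature channels do not match training channels",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ",")),
         if (!length(missing) && !length(extra)) "; order differs")
  }
  scores <- forestScores(model@model, rangerData(fm))
  stats::setNames(scores, pairIndex(fm))
}

#' Threshold a score table into the predicted-FI set
#'
#' Pairs with score greater than or equal to `cutoff` (inclusive, default
#' 0.8) form the predicted functional interactions.
#'
#' @param scores Named numeric vector (pair key -> score).
#' @param cutoff Score cutoff in `[0,1]`, default 0.8.
#' @return Character vector of retained pair keys.
#' @export
thresholdPredictions <- function(scores, cutoff = 0.8) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (length(scores) == 0) return(character(0))
  sort(names(scores)[scores >= cutoff], method = "radix")
}

#' Ranked feature importances of a trained classifier
#'
#' Impurity importances normalised to sum to 1 and sorted in descending
#' order; deterministic under the configuration's fixed random state.
#'
#' @param model An [FIClassifier-class].
#' @return data.frame with columns `channel`, `importance`.
#' @export
featureImportance <- function(model) {
  if (!methods::is(model, "FIClassifier") || is.null(model@model))
    stop("model is not a trained FIClassifier")
  imp <- ranger::importance(model@model)
  names(imp) <- model@channels[match(names(imp), make.names(model@channels))]
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else imp
  ord <- order(-imp, names(imp), method = "radix")
  data.frame(channel = names(imp)[ord], importance = as.numeric(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Persist / reload a trained FI classifier
#'
#' The on-disk format is a versioned blob embedding the channel names;
#' loading refuses blobs whose version is unknown. Scores are invariant
#' across save/reload.
#'
#' @param model An [FIClassifier-class].
#' @param path File path.
#' @return `saveFIClassifier`: `path` invisibly; `loadFIClassifier`: the
#'   restored [FIClassifier-class].
#' @export
saveFIClassifier <- function(model, path) {
  saveRDS(list(format = "darkpath-fi-classifier", version = 1L,
               channels = model@channels, config = model@config,
               model = model@model), path)
  invisible(path)
}

#' @rdname saveFIClassifier
#' @export
loadFIClassifier <- function(path) {
  blob <- readRDS(path)
  if (!identical(blob$format, "darkpath-fi-classifier") ||
      !identical(blob$version, 1L))
    stop("not a recognised FI classifier blob: ", path)
  new("FIClassifier", model = blob$model, channels = blob$channels,
      config = blob$config)
}
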