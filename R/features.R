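# Feature-channel construction and vetting: expression QC (RIN/group
# filters, PCA outlier flagging), cpm + Spearman co-expression, top-percentile
# pair selection, ortholog mapping, odds-ratio vetting and feature-matrix
# assembly.

#' Construct a FeatureChannel
#' @param name Channel name.
#' @param category One of `coexpression`, `ppi`, `similarity`, `domain`,
#'   `gobp`.
#' @param pairs Character vector of pair keys (canonicalised and
#'   deduplicated here).
#' @param meta Optional metadata list.
#' @return A [FeatureChannel-class].
#' @export
featureChannel <- function(name, category, pairs, meta = list()) {
  pairs <- unique(as.character(pairs))
  if (length(pairs)) {
    m <- splitPairKey(pairs)
    keep <- m[, 1] != m[, 2]
    pairs <- sort(unique(pairKey(m[keep, 1], m[keep, 2])), method = "radix")
  }
  new("FeatureChannel", name = name, category = category, pairs = pairs,
      meta = meta)
}

#' Build an expression container from counts and sample metadata
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param rin Numeric RNA-integrity numbers per sample (NA allowed).
#' @param group Tissue/cancer label per sample.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` and colData columns `rin`, `group`.
#' @export
expressionSE <- function(counts, rin = rep(NA_real_, ncol(counts)),
                         group = rep("all", ncol(counts))) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(rin = as.numeric(rin),
                                   group = as.character(group),
                                   row.names = colnames(counts))
  )
}

#' Filter samples by RNA integrity and group size
#'
#' Samples with RIN less than or equal to `minRIN` are removed (the boundary
#' is inclusive), then any group left with fewer than `minSamples` samples
#' is removed entirely. Samples with missing RIN pass the RIN filter.
#'
#' @param se Expression [SummarizedExperiment::SummarizedExperiment]
#'   (see [expressionSE()]).
#' @param minRIN RIN threshold, default 6.0.
#' @param minSamples Minimum group size, default 30.
#' @return The filtered SummarizedExperiment. Warns (rather than silently
#'   returning) when no samples survive.
#' @export
filterSamples <- function(se, minRIN = 6.0, minSamples = 30) {
  cd <- SummarizedExperiment::colData(se)
  keep <- is.na(cd$rin) | cd$rin > minRIN
  se2 <- se[, keep]
  grp <- SummarizedExperiment::colData(se2)$group
  sizes <- table(grp)
  keepGrp <- names(sizes)[sizes >= minSamples]
  se2 <- se2[, grp %in% keepGrp]
  if (ncol(se2) == 0) warning("all samples removed by RIN/group-size filters")
  se2
}

cpmMatrix <- function(se) {
  edgeR::cpm(SummarizedExperiment::assay(se, "counts"))
}

#' Flag principal-component outlier samples
#'
#' Computes log2(cpm + 1), centres each gene, projects samples onto the
#' first principal component, standardises the scores and orients the
#' component so the heavier tail is positive; samples with z-score greater
#' than or equal to `zCut` are flagged.
#'
#' @param se Expression SummarizedExperiment (at least 3 samples).
#' @param zCut z-score threshold, default 3.0 (inclusive).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flagOutliersPCA <- function(se, zCut = 3.0) {
  if (ncol(se) < 3) stop("need at least 3 samples for PCA outlier flagging")
  x <- log2(cpmMatrix(se) + 1)
  xc <- x - rowMeans(x)                 # centre genes
  keep <- apply(xc, 1, function(v) any(v != 0))
  xc <- xc[keep, , drop = FALSE]
  if (nrow(xc) == 0) return(character(0))  # identical samples
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  sds <- stats::sd(s)
  if (sds == 0) return(character(0))
  z <- (s - mean(s)) / sds
  if (sum(z^3) < 0) z <- -z             # heavier tail positive
  colnames(se)[z >= zCut]
}

#' Gene-gene co-expression matrix (cpm + Spearman)
#'
#' Normalises counts to counts-per-million and computes pairwise Spearman
#' correlations across samples. Outliers are expected to be removed
#' beforehand (see [flagOutliersPCA()]). Correlations involving a
#' constant-expression gene are undefined and recorded as `NA`, not 0.
#'
#' @param se Expression SummarizedExperiment with at least 2 samples.
#' @param method Correlation method, default `"spearman"`.
#' @return Symmetric gene x gene correlation matrix with unit diagonal.
#' @export
coexpressionMatrix <- function(se, method = "spearman") {
  if (ncol(se) < 2) stop("need at least 2 samples")
  cpm <- cpmMatrix(se)
  cc <- suppressWarnings(stats::cor(t(cpm), method = method))
  diag(cc) <- 1
  cc
}

#' Select the top-percentile gene pairs of a correlation matrix
#'
#' Takes the `ceiling(pct/100 * P)` highest-valued unordered off-diagonal
#' pairs among the P candidate pairs (NA correlations are excluded from the
#' candidates). Ties are broken deterministically by (value descending,
#' canonical pair key ascending).
#'
#' @param corr Symmetric correlation matrix with dimnames.
#' @param pct Percentile in (0, 100), e.g. `0.1` for the top 0.1%.
#' @param positiveOnly Restrict candidates to pairs with positive
#'   correlation (used for the co-expression validation channel).
#' @param name,category Passed to the resulting [FeatureChannel-class].
#' @return A [FeatureChannel-class] of the selected pairs.
#' @export
topPercentilePairs <- function(corr, pct, positiveOnly = FALSE,
                               name = sprintf("coexpr_top%g", pct),
                               category = "coexpression") {
  stopifnot(pct > 0, pct < 100)
  g <- rownames(corr)
  if (is.null(g) || length(g) < 2)
    return(featureChannel(name, category, character(0)))
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[ut]
  keys <- pairKey(g[ut[, 1]], g[ut[, 2]])
  ok <- !is.na(vals)
  if (positiveOnly) ok <- ok & vals > 0
  vals <- vals[ok]; keys <- keys[ok]
  P <- length(vals)
  if (P == 0) return(featureChannel(name, category, character(0)))
  n <- ceiling(pct / 100 * P)
  ord <- order(-vals, keys, method = "radix")
  featureChannel(name, category, keys[ord[seq_len(n)]])
}

#' Map a pair channel to human symbols through an ortholog table
#'
#' Each source pair expands to the cross-product of its members' human
#' orthologs; self-pairs are dropped; the result is canonicalised and
#' deduplicated. Pairs with an unmapped member are silently dropped and
#' counted in the channel's `meta$droppedPairs`.
#'
#' @param channel A [FeatureChannel-class] over source-organism gene ids.
#' @param orthologMap Named list: source gene -> character vector of human
#'   symbols (or a two-column data.frame `source_gene`, `human_symbol`).
#' @return A [FeatureChannel-class] over human symbols.
#' @export
mapPairsViaOrthologs <- function(channel, orthologMap) {
  if (is.data.frame(orthologMap)) {
    orthologMap <- split(as.character(orthologMap[[2]]),
                         as.character(orthologMap[[1]]))
  }
  dropped <- 0L
  out <- character(0)
  if (length(channel@pairs)) {
    m <- splitPairKey(channel@pairs)
    for (i in seq_len(nrow(m))) {
      ha <- orthologMap[[m[i, 1]]]
      hb <- orthologMap[[m[i, 2]]]
      if (is.null(ha) || is.null(hb)) { dropped <- dropped + 1L; next }
      g <- expand.grid(a = ha, b = hb, stringsAsFactors = FALSE)
      g <- g[g$a != g$b, , drop = FALSE]
      if (nrow(g) == 0) { dropped <- dropped + 1L; next }
      out <- c(out, pairKey(g$a, g$b))
    }
  }
  featureChannel(channel@name, channel@category, out,
                 meta = c(channel@meta, list(droppedPairs = dropped)))
}

#' Odds ratio of a feature channel against reference FIs
#'
#' Cross-tabulates channel membership against reference-FI membership over
#' a pair universe: `a` = channel & FI, `b` = channel only, `c` = FI only,
#' `d` = neither; odds ratio = (a d)/(b c). If any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to all four cells so vetting
#' stays defined for sparse channels.
#'
#' @param channel A [FeatureChannel-class] (pairs must lie in `universe`).
#' @param fis Character vector of reference-FI pair keys (subset of
#'   `universe`).
#' @param universe Character vector of all candidate pair keys.
#' @return One-row data.frame: `channel`, `a`, `b`, `c`, `d`, `odds_ratio`.
#' @export
pairwiseOddsRatio <- function(channel, fis, universe) {
  if (length(universe) == 0) stop("empty pair universe")
  ch <- channel@pairs
  if (length(setdiff(ch, universe)))
    stop("channel pairs outside the universe")
  if (length(setdiff(fis, universe)))
    stop("FI pairs outside the universe")
  a <- length(intersect(ch, fis))
  b <- length(ch) - a
  cc <- length(fis) - a
  d <- length(universe) - a - b - cc
  orv <- if (min(a, b, cc, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  data.frame(channel = channel@name, a = a, b = b, c = cc, d = d,
             odds_ratio = orv, stringsAsFactors = FALSE)
}

#' Vet feature channels by odds ratio
#'
#' Retains channels whose odds ratio against the reference FIs is strictly
#' greater than `threshold` (default 5.0); a report row is emitted for every
#' channel, retained or not.
#'
#' @param channels List of [FeatureChannel-class] objects.
#' @param fis Reference-FI pair keys.
#' @param universe Pair universe (see [pairUniverse()] for the default
#'   convention).
#' @param threshold Strict odds-ratio cutoff, default 5.0.
#' @return List with `selected` (channel names retained) and `reports`
#'   (data.frame, one row per channel with a `selected` flag).
#' @export
selectFeatures <- function(channels, fis, universe, threshold = 5.0) {
  reports <- do.call(rbind, lapply(channels, pairwiseOddsRatio,
                                   fis = fis, universe = universe))
  if (is.null(reports)) {
    reports <- data.frame(channel = character(0), a = integer(0),
                          b = integer(0), c = integer(0), d = integer(0),
                          odds_ratio = numeric(0), selected = logical(0))
    return(list(selected = character(0), reports = reports))
  }
  reports$selected <- reports$odds_ratio > threshold
  list(selected = reports$channel[reports$selected], reports = reports)
}

#' Default pair universe for odds-ratio vetting
#'
#' All unordered pairs over the genes covered by both the channel's gene
#' space and the FI gene space. The published vetting universe is unstated;
#' this intersection convention is configurable by passing any universe to
#' [pairwiseOddsRatio()] directly.
#'
#' @param channel A [FeatureChannel-class].
#' @param fis Reference-FI pair keys.
#' @return Character vector of pair keys.
#' @export
pairUniverse <- function(channel, fis) {
  genes <- intersect(pairGenes(channel@pairs), pairGenes(fis))
  allPairKeys(genes)
}

#' Assemble the binary pair x channel feature matrix
#'
#' @param pairIdx Character vector of canonical pair keys (row order kept in
#'   canonical sorted order).
#' @param channels List of [FeatureChannel-class] objects (column order =
#'   input order).
#' @param labels Optional integer 0/1 FI labels aligned with `pairIdx`.
#' @return A [FeatureMatrix-class].
#' @export
assembleFeatureMatrix <- function(pairIdx, channels, labels = NULL) {
  nms <- vapply(channels, function(ch) ch@name, character(1))
  if (anyDuplicated(nms)) stop("duplicate channel names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  ord <- order(pairIdx, method = "radix")
  pairIdx <- pairIdx[ord]
  if (!is.null(labels)) labels <- as.integer(labels)[ord]
  vals <- matrix(0L, nrow = length(pairIdx), ncol = length(channels))
  for (j in seq_along(channels)) {
    vals[, j] <- as.integer(pairIdx %in% channels[[j]]@pairs)
  }
  new("FeatureMatrix", pairIndex = pairIdx, channels = nms, values = vals,
      labels = labels)
}
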