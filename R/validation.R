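# Agreement statistics between scoring channels: per-gene Pearson
# correlations, skew/proportion summaries, standard group-difference tests,
# and the co-expression-based pathway scoring used for the single-cell
# validation.

#' Per-gene score vector
#' @param gene Gene symbol.
#' @param pathwayIds Pathway ids.
#' @param scores Numeric scores aligned with `pathwayIds`.
#' @return A classed list (`GeneScoreVector`).
#' @export
geneScoreVector <- function(gene, pathwayIds, scores) {
  stopifnot(length(pathwayIds) == length(scores))
  structure(list(gene = gene,
                 scores = stats::setNames(as.numeric(scores),
                                          as.character(pathwayIds))),
            class = "GeneScoreVector")
}

#' Pearson correlation between two score vectors of one gene
#'
#' Intersects the two vectors' pathway ids; genes sharing fewer than
#' `minPathways` pathways (default 10) are excluded (a missing record, not
#' a correlation of 0), as are zero-variance vectors.
#'
#' @param a,b [geneScoreVector()] objects over the same gene.
#' @param minPathways Minimum shared pathways, default 10.
#' @return One-row data.frame `gene`, `n_pathways`, `r`, `p`, `reason`
#'   (`reason` is `NA` for a retained record, otherwise why it is missing).
#' @export
perGeneCorrelation <- function(a, b, minPathways = 10L) {
  if (!identical(a$gene, b$gene)) stop("score vectors are for different genes")
  shared <- intersect(names(a$scores), names(b$scores))
  rec <- function(n, r, p, reason) data.frame(
    gene = a$gene, n_pathways = n, r = r, p = p, reason = reason,
    stringsAsFactors = FALSE)
  if (length(shared) < minPathways)
    return(rec(length(shared), NA_real_, NA_real_, "too few shared pathways"))
  x <- a$scores[shared]
  y <- b$scores[shared]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < minPathways)
    return(rec(length(x), NA_real_, NA_real_, "too few shared pathways"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(rec(length(x), NA_real_, NA_real_, "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  rec(length(x), unname(ct$estimate), ct$p.value, NA_character_)
}

#' Correlation records for all genes shared by two score tables
#'
#' @param tableA,tableB Numeric gene x pathway matrices (e.g. enrichment
#'   scores from two channels).
#' @param minPathways Minimum shared pathways per gene, default 10.
#' @return data.frame of stacked [perGeneCorrelation()] records.
#' @export
correlateScoreTables <- function(tableA, tableB, minPathways = 10L) {
  genes <- intersect(rownames(tableA), rownames(tableB))
  out <- lapply(genes, function(g) {
    a <- geneScoreVector(g, colnames(tableA), tableA[g, ])
    b <- geneScoreVector(g, colnames(tableB), tableB[g, ])
    perGeneCorrelation(a, b, minPathways = minPathways)
  })
  do.call(rbind, out)
}

#' Skew summary of per-gene correlations
#'
#' Counts positive vs negative correlations, tests the counts against an
#' even split with an exact two-sided binomial proportion test, and
#' compares `-log10(p)` and `|r|` between the positive-r and negative-r
#' groups with Welch t and Mann-Whitney tests (all two-sided). When one
#' sign group is empty the two-sample entries are reported missing.
#'
#' @param records data.frame from [correlateScoreTables()] (needs >= 2
#'   retained records).
#' @return List: `n_pos`, `n_neg`, `proportion_p`, `neglogp_welch_p`,
#'   `neglogp_mw_p`, `absr_welch_p`, `absr_mw_p`.
#' @export
skewSummary <- function(records) {
  rec <- records[is.finite(records$r), , drop = FALSE]
  if (nrow(rec) < 2) stop("need at least 2 correlation records")
  pos <- rec$r > 0
  neg <- rec$r < 0
  nPos <- sum(pos)
  nNeg <- sum(neg)
  propP <- stats::binom.test(nPos, nPos + nNeg, p = 0.5,
                             alternative = "two.sided")$p.value
  two <- function(v) {
    if (nPos == 0 || nNeg == 0)
      return(c(welch = NA_real_, mw = NA_real_))
    vp <- v[pos]; vn <- v[neg]
    w <- tryCatch(stats::t.test(vp, vn, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    m <- tryCatch(suppressWarnings(stats::wilcox.test(vp, vn)$p.value),
                  error = function(e) NA_real_)
    c(welch = w, mw = m)
  }
  nlp <- two(-log10(pmax(rec$p, 1e-300)))
  ar <- two(abs(rec$r))
  list(n_pos = nPos, n_neg = nNeg, proportion_p = propP,
       neglogp_welch_p = unname(nlp["welch"]), neglogp_mw_p = unname(nlp["mw"]),
       absr_welch_p = unname(ar["welch"]), absr_mw_p = unname(ar["mw"]))
}

#' Standard two-sided group-difference tests
#'
#' @param values Numeric vector.
#' @param groups Group labels (exactly 2 groups for `welch_t` and
#'   `mann_whitney`, >= 2 for `anova`).
#' @param kind `"welch_t"`, `"anova"` or `"mann_whitney"`.
#' @return List `statistic`, `p_value`.
#' @export
groupDifferenceTests <- function(values, groups,
                                 kind = c("welch_t", "anova", "mann_whitney")) {
  kind <- match.arg(kind)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  ng <- nlevels(groups)
  if (kind == "anova") {
    if (ng < 2) stop("anova needs >= 2 groups")
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1]]
    return(list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1]))
  }
  if (ng != 2) stop(kind, " needs exactly 2 groups")
  sp <- split(values, groups)
  if (kind == "welch_t") {
    tt <- tryCatch(stats::t.test(sp[[1]], sp[[2]], var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {  # constant data: t.test refuses
      eq <- isTRUE(all.equal(mean(sp[[1]]), mean(sp[[2]])))
      return(list(statistic = if (eq) 0 else Inf, p_value = if (eq) 1 else 0))
    }
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value))
  }
  wt <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]],
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Co-expression-based interacting-pathway scores
#'
#' The single-cell-style validation channel: computes gene-gene
#' correlations on cpm-normalised expression, keeps the top `pct` percent
#' of positively correlated pairs as functional-correlation pairs, treats
#' each gene's selected partners as its gene set, and scores pathways with
#' the same binomial-enrichment machinery used for predicted FIs
#' ([interactingPathways()]).
#'
#' @param se Expression SummarizedExperiment (cells or samples as columns).
#' @param db A [PathwayDatabase-class].
#' @param pct Top percentile of positive pairs, default 0.1.
#' @param universe Background genes, default all genes in `db`.
#' @param method Correlation method, default `"spearman"`.
#' @return Numeric gene x pathway matrix of enrichment scores (genes with
#'   no selected partner are omitted).
#' @export
coexpressionPathwayScores <- function(se, db, pct = 0.1,
                                      universe = dbGeneSymbols(db),
                                      method = "spearman") {
  cc <- coexpressionMatrix(se, method = method)
  ch <- topPercentilePairs(cc, pct, positiveOnly = TRUE)
  enrichmentScoreTable(ch@pairs, db, universe = universe)
}

#' Gene x pathway enrichment-score table from a pair set
#'
#' @param fiSet Pair keys (predicted FIs or co-expression pairs).
#' @param db A [PathwayDatabase-class].
#' @param genes Genes to score, default all genes in `fiSet`.
#' @param universe Background genes.
#' @return Numeric matrix genes x pathways of enrichment scores.
#' @export
enrichmentScoreTable <- function(fiSet, db, genes = pairGenes(fiSet),
                                 universe = dbGeneSymbols(db)) {
  rec <- interactingPathwaysAll(fiSet, db, genes = genes, universe = universe)
  pws <- sort(unique(rec$pathway_id), method = "radix")
  genes <- sort(unique(rec$gene), method = "radix")
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(pws),
                dimnames = list(genes, pws))
  out[cbind(match(rec$gene, genes), match(rec$pathway_id, pws))] <-
    rec$enrichment_score
  out
}

#' Min-max scale scores to the unit interval
#'
#' Used for displaying the three interacting-pathway scores on a common
#' `[0,1]` axis. A constant vector maps to 0.5 by convention.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Scaled values in `[0,1]` (NA preserved).
#' @export
scaleScores <- function(values) {
  if (length(values) == 0) stop("empty input")
  fin <- is.finite(values)
  if (!any(fin)) stop("no finite values")
  rng <- range(values[fin])
  out <- values
  if (rng[1] == rng[2]) {
    out[fin] <- 0.5
  } else {
    out[fin] <- (values[fin] - rng[1]) / (rng[2] - rng[1])
  }
  out
}
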