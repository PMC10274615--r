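# Interacting-pathway enrichment: binomial tail p-values over a gene's
# predicted FI partners, Benjamini-Hochberg adjustment per gene across
# pathways, enrichment score = -log10(FDR).

#' One-sided binomial enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, K/N)`: the chance
#' of observing at least `k` of a gene's `n` FI partners inside a pathway of
#' size `K` drawn from a universe of `N` genes.
#'
#' @param k Observed overlap (0 <= k <= n).
#' @param n Number of FI partners in the universe.
#' @param K Pathway gene-set size (0 < K <= N).
#' @param N Universe size.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
binomialPValue <- function(k, n, K, N) {
  if (any(k < 0) || any(k > n) || any(K <= 0) || any(K > N) || any(n > N) ||
      any(n < 0))
    stop("invalid counts: need 0 <= k <= n <= N and 0 < K <= N")
  stats::pbinom(k - 1, size = n, prob = K / N, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up procedure: sorted p-values are scaled by m/i, a reverse
#' cumulative minimum enforces monotonicity, values are capped at 1 and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR values, same length and order.
#' @export
bhAdjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(q)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Interacting pathways of one gene
#'
#' Performs pathway enrichment for a gene using its predicted FI partners as
#' the query gene set: for every pathway with a non-empty gene set, a
#' one-sided binomial p-value ([binomialPValue()]) is computed, BH-adjusted
#' across pathways within the gene, and converted to the enrichment score
#' `-log10(FDR)` (FDR floored at 1e-300 so scores stay finite). Partners
#' are intersected with the universe before `n` is computed; the overlap
#' counts genes, not pairs.
#'
#' @param gene Gene symbol.
#' @param fiSet Character vector of predicted-FI pair keys.
#' @param db A [PathwayDatabase-class].
#' @param universe Background gene set; default all genes in `db`
#'   (configurable, e.g. to all protein-coding genes).
#' @param geneSets Optional precomputed [pathwayGeneSets()] to avoid
#'   recomputation across many genes.
#' @return data.frame with one row per pathway: `gene`, `pathway_id`,
#'   `pathway_name`, `overlap`, `partners_in_universe`, `pathway_size`,
#'   `universe_size`, `p_value`, `fdr`, `enrichment_score`,
#'   `avg_activation`, `avg_inhibition` (simulation columns NA here; see
#'   [simulationScores()]); sorted by enrichment score descending. A gene
#'   with no partners in the universe yields an empty frame with a warning.
#' @export
interactingPathways <- function(gene, fiSet, db,
                                universe = dbGeneSymbols(db),
                                geneSets = NULL) {
  emptyRec <- data.frame(
    gene = character(0), pathway_id = character(0), pathway_name = character(0),
    overlap = integer(0), partners_in_universe = integer(0),
    pathway_size = integer(0), universe_size = integer(0),
    p_value = numeric(0), fdr = numeric(0), enrichment_score = numeric(0),
    avg_activation = numeric(0), avg_inhibition = numeric(0),
    stringsAsFactors = FALSE)
  partners <- intersect(pairPartners(gene, fiSet), universe)
  if (length(partners) == 0) {
    warning("gene ", gene, " has no predicted FI partners in the universe")
    return(emptyRec)
  }
  if (is.null(geneSets)) geneSets <- pathwayGeneSets(db)
  geneSets <- lapply(geneSets, intersect, y = universe)
  geneSets <- geneSets[vapply(geneSets, length, integer(1)) > 0]
  if (length(geneSets) == 0) return(emptyRec)
  N <- length(unique(universe))
  n <- length(partners)
  K <- vapply(geneSets, length, integer(1))
  k <- vapply(geneSets, function(s) length(intersect(partners, s)), integer(1))
  p <- binomialPValue(k, n, K, N)
  fdr <- bhAdjust(p)
  rec <- data.frame(
    gene = gene, pathway_id = names(geneSets),
    pathway_name = vapply(names(geneSets), function(id)
      pathwayName(db, id), character(1)),
    overlap = k, partners_in_universe = n, pathway_size = K,
    universe_size = N, p_value = p, fdr = fdr,
    enrichment_score = -log10(pmax(fdr, 1e-300)),
    avg_activation = NA_real_, avg_inhibition = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
  rec[order(-rec$enrichment_score, rec$fdr, rec$pathway_id,
            method = "radix"), , drop = FALSE]
}

#' Interacting pathways for every gene of a predicted FI set
#'
#' Convenience wrapper applying [interactingPathways()] to each gene that
#' appears in `fiSet` (or a supplied gene list), with gene sets computed
#' once.
#'
#' @param fiSet Predicted-FI pair keys.
#' @param db A [PathwayDatabase-class].
#' @param genes Genes to score; default every gene occurring in `fiSet`.
#' @param universe Background gene set, as in [interactingPathways()].
#' @return data.frame of stacked per-gene records.
#' @export
interactingPathwaysAll <- function(fiSet, db, genes = pairGenes(fiSet),
                                   universe = dbGeneSymbols(db)) {
  gs <- pathwayGeneSets(db)
  out <- lapply(genes, function(g)
    suppressWarnings(interactingPathways(g, fiSet, db, universe = universe,
                                         geneSets = gs)))
  do.call(rbind, out)
}
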