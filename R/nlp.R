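# Literature-based pathway annotation score: gene-abstract matching by
# alias, hierarchical event-summation embedding similarity, and top-k
# abstract averaging. The embedding provider is pluggable: any object with
# $dim and a deterministic $embed(text) honours the contract; the package
# ships a deterministic hash-based pseudo-embedder used by the synthetic
# corpus and the tests.

#' Deterministic hash-based pseudo-embedding provider
#'
#' Bag-of-words embedding: each lowercase alphanumeric token is hashed into
#' one of `nBuckets` buckets, each bucket owns a fixed pseudo-random
#' direction in `dim`-dimensional space (a deterministic trigonometric
#' construction, no RNG state touched), and a text embeds to the sum of its
#' tokens' directions. Same text, same vector - always.
#'
#' @param dim Embedding dimension, default 384 (matching the sentence-
#'   embedding models typically used for abstract embedding).
#' @param nBuckets Number of hash buckets, default 4096.
#' @return An embedding provider: list with `dim` and `embed(text)`.
#' @export
pseudoEmbedder <- function(dim = 384L, nBuckets = 4096L) {
  dim <- as.integer(dim)
  nBuckets <- as.integer(nBuckets)
  # fixed projection: V[dim, nBuckets], entries in (-1, 1)
  raw <- sin(outer(seq_len(dim) * 12.9898, seq_len(nBuckets) * 78.233,
                   `+`)) * 43758.5453
  V <- 2 * (raw - floor(raw)) - 1
  cache <- new.env(parent = emptyenv())
  hashToken <- function(tok) {
    h <- mget(tok, envir = cache, ifnotfound = list(NULL))[[1]]
    if (!is.null(h)) return(h)
    v <- 0
    for (b in utf8ToInt(tok)) v <- (v * 31 + b) %% 1048573
    v <- as.integer(v %% nBuckets) + 1L
    assign(tok, v, envir = cache)
    v
  }
  embed <- function(text) {
    toks <- tokenizeText(text)
    if (length(toks) == 0) return(numeric(dim))
    buckets <- vapply(toks, hashToken, integer(1))
    tab <- table(buckets)
    idx <- as.integer(names(tab))
    as.numeric(V[, idx, drop = FALSE] %*% as.numeric(tab))
  }
  structure(list(dim = dim, embed = embed), class = "EmbeddingProvider")
}

tokenizeText <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Match abstracts mentioning a gene
#'
#' Simple text matching: an abstract matches when it contains any alias as
#' a word-boundary-delimited token. All-uppercase aliases (gene symbols)
#' are matched case-sensitively; mixed-case or multi-word aliases (protein
#' names) case-insensitively. Results are ordered by pmid.
#'
#' @param corpus data.frame with columns `pmid`, `text`.
#' @param aliases Character vector of aliases (must be non-empty and should
#'   include the primary symbol).
#' @return The matching rows of `corpus`, ordered by `pmid`.
#' @export
matchAbstracts <- function(corpus, aliases) {
  aliases <- unique(aliases[nzchar(aliases)])
  if (length(aliases) == 0) stop("empty alias set")
  hit <- rep(FALSE, nrow(corpus))
  for (al in aliases) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", al)
    pat <- paste0("\\b", esc, "\\b")
    caseSensitive <- identical(al, toupper(al))
    hit <- hit | grepl(pat, corpus$text, perl = TRUE,
                       ignore.case = !caseSensitive)
  }
  out <- corpus[hit, , drop = FALSE]
  out[order(out$pmid, method = "radix"), , drop = FALSE]
}

# summation texts of a pathway and ALL events (sub-pathways and reactions)
# inside it; events without summation text are skipped.
eventSummations <- function(db, pathwayId) {
  out <- character(0)
  visit <- function(id) {
    if (id %in% names(db@pathways)) {
      p <- db@pathways[[id]]
      if (!is.na(p$summation) && nzchar(p$summation)) out[[id]] <<- p$summation
      for (ch in p$children) visit(ch)
    } else if (id %in% names(db@reactions)) {
      r <- db@reactions[[id]]
      if (!is.na(r$summation) && nzchar(r$summation)) out[[id]] <<- r$summation
    } else stop("unknown event id: ", id)
  }
  visit(pathwayId)
  out
}

# embeddings of a pathway's event summations, cached per (db, provider) call
# site through an optional environment.
eventEmbeddings <- function(db, pathwayId, provider, cache = NULL) {
  key <- paste0("ev_", pathwayId)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  texts <- eventSummations(db, pathwayId)
  if (length(texts) == 0)
    stop("pathway ", pathwayId, " has no embeddable summation text")
  em <- vapply(texts, provider$embed, numeric(provider$dim))
  em <- matrix(em, nrow = provider$dim,
               dimnames = list(NULL, names(texts)))
  if (!is.null(cache)) cache[[key]] <- em
  em
}

#' Hierarchical event-embedding similarity of a pathway to an abstract
#'
#' Cosine similarity between the abstract's embedding and the embeddings of
#' the pathway's summation plus the summations of every event (sub-pathway
#' and reaction) it contains, averaged with equal weight. Events without
#' summation text are skipped (not counted in the denominator).
#'
#' @param pathwayId Pathway id.
#' @param abstractVec Numeric embedding of the abstract.
#' @param db A [PathwayDatabase-class].
#' @param provider An embedding provider (see [pseudoEmbedder()]).
#' @return Mean cosine similarity in `[-1, 1]`.
#' @export
eventSimilarity <- function(pathwayId, abstractVec, db, provider) {
  em <- eventEmbeddings(db, pathwayId, provider)
  mean(apply(em, 2, cosineSim, y = abstractVec))
}

# similarity matrix abstracts x pathways, computed once for a corpus
abstractPathwaySims <- function(corpus, pathwaySet, db, provider) {
  cache <- new.env(parent = emptyenv())
  absVec <- vapply(corpus$text, provider$embed, numeric(provider$dim),
                   USE.NAMES = FALSE)
  absVec <- matrix(absVec, nrow = provider$dim)
  sims <- matrix(NA_real_, nrow = nrow(corpus), ncol = length(pathwaySet),
                 dimnames = list(corpus$pmid, pathwaySet))
  for (pw in pathwaySet) {
    em <- eventEmbeddings(db, pw, provider, cache = cache)
    sims[, pw] <- vapply(seq_len(nrow(corpus)), function(i)
      mean(apply(em, 2, cosineSim, y = absVec[, i])), numeric(1))
  }
  sims
}

#' Literature annotation score of a gene for a pathway
#'
#' Among the abstracts matching the gene's aliases, ranks abstracts by
#' their average [eventSimilarity()] across all pathways under analysis,
#' keeps at most `k` top-ranked abstracts (default 1,000) and returns the
#' mean similarity of the kept abstracts to the queried pathway.
#'
#' @param gene Gene symbol.
#' @param pathwayId Pathway to score.
#' @param corpus data.frame `pmid`, `text`.
#' @param db A [PathwayDatabase-class].
#' @param provider Embedding provider.
#' @param aliases Alias vector for the gene (default: the symbol itself).
#' @param k Maximum abstracts kept, default 1000.
#' @param pathwaySet Pathways "under analysis" used for the ranking
#'   average; default all pathways in `db`.
#' @return The annotation score, or `NA` when the gene matches no abstract
#'   (a missing value, not 0).
#' @export
annotationScore <- function(gene, pathwayId, corpus, db, provider,
                            aliases = gene, k = 1000L,
                            pathwaySet = pathwayIds(db)) {
  matched <- matchAbstracts(corpus, aliases)
  if (nrow(matched) == 0) return(NA_real_)
  sims <- abstractPathwaySims(matched, union(pathwaySet, pathwayId), db,
                              provider)
  rankAvg <- rowMeans(sims[, pathwaySet, drop = FALSE])
  ord <- order(-rankAvg, matched$pmid, method = "radix")
  keep <- ord[seq_len(min(k, length(ord)))]
  mean(sims[keep, pathwayId])
}

#' Gene x pathway table of literature annotation scores
#'
#' Applies the [annotationScore()] procedure to every (gene, pathway)
#' combination, sharing the abstract and event embeddings across genes.
#' Genes with no matched abstracts get a row of `NA` (missing, not 0).
#'
#' @param genes Character vector of gene symbols.
#' @param pathways Character vector of pathway ids (also the "pathways
#'   under analysis" for ranking).
#' @param corpus data.frame `pmid`, `text`.
#' @param db A [PathwayDatabase-class].
#' @param provider Embedding provider.
#' @param aliasTable Optional data.frame `symbol`, `alias`; a gene's aliases
#'   default to its symbol.
#' @param k Maximum abstracts kept per gene, default 1000.
#' @return Numeric matrix genes x pathways; invariant to corpus row order.
#' @export
nlpValidationScores <- function(genes, pathways, corpus, db, provider,
                                aliasTable = NULL, k = 1000L) {
  corpus <- corpus[order(corpus$pmid, method = "radix"), , drop = FALSE]
  sims <- abstractPathwaySims(corpus, pathways, db, provider)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(pathways),
                dimnames = list(genes, pathways))
  for (g in genes) {
    aliases <- g
    if (!is.null(aliasTable))
      aliases <- unique(c(g, aliasTable$alias[aliasTable$symbol == g]))
    matched <- matchAbstracts(corpus, aliases)
    if (nrow(matched) == 0) next
    idx <- match(matched$pmid, corpus$pmid)
    rankAvg <- rowMeans(sims[idx, , drop = FALSE])
    ord <- order(-rankAvg, matched$pmid, method = "radix")
    keep <- idx[ord[seq_len(min(k, length(ord)))]]
    out[g, ] <- colMeans(sims[keep, , drop = FALSE])
  }
  out
}
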