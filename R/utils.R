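# Internal helpers shared across modules: canonical pair keys, seed scoping,
# cosine similarity.

PAIR_SEP <- "|"

#' Canonical key for an unordered gene pair
#'
#' Gene pairs are represented everywhere in darkpath as a single string
#' `"A|B"` with the two symbols in lexicographic (C-locale) order, so that a
#' pair compares equal regardless of orientation.
#'
#' @param a,b Character vectors of gene symbols (recycled to common length).
#' @return Character vector of canonical pair keys.
#' @examples
#' pairKey("TP53", "MDM2")  # "MDM2|TP53"
#' @export
pairKey <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (any(a == b)) stop("self-pairs are not allowed in pair keys")
  # vectorised locale-independent (C-collation) comparison via radix ranks
  n <- length(a)
  s <- c(a, b)
  rk <- integer(2 * n)
  rk[order(s, method = "radix")] <- seq_len(2 * n)
  swap <- rk[seq_len(n)] > rk[n + seq_len(n)]
  ifelse(swap, paste(b, a, sep = PAIR_SEP), paste(a, b, sep = PAIR_SEP))
}

#' Split canonical pair keys back into a two-column matrix
#' @param keys Character vector of `"A|B"` pair keys.
#' @return Character matrix with columns `geneA`, `geneB`.
#' @export
splitPairKey <- function(keys) {
  parts <- strsplit(keys, PAIR_SEP, fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  colnames(m) <- c("geneA", "geneB")
  m
}

#' All unordered pair keys over a gene universe
#' @param genes Character vector of gene symbols.
#' @return Character vector of `choose(n, 2)` canonical pair keys in
#'   canonical (radix-sorted) order.
#' @export
allPairKeys <- function(genes) {
  genes <- sort(unique(as.character(genes)), method = "radix")
  n <- length(genes)
  if (n < 2) return(character(0))
  idx <- utils::combn(n, 2)
  paste(genes[idx[1, ]], genes[idx[2, ]], sep = PAIR_SEP)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Cosine similarity between two numeric vectors
#'
#' Returns 0 when either vector has zero norm (an empty/untokenisable text
#' embeds to the zero vector).
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosineSim <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# genes appearing in a set of pair keys
pairGenes <- function(keys) {
  if (length(keys) == 0) return(character(0))
  sort(unique(as.vector(splitPairKey(keys))), method = "radix")
}

# partners of `gene` among pair keys
pairPartners <- function(gene, keys) {
  if (length(keys) == 0) return(character(0))
  m <- splitPairKey(keys)
  hit <- m[, 1] == gene | m[, 2] == gene
  if (!any(hit)) return(character(0))
  p <- ifelse(m[hit, 1] == gene, m[hit, 2], m[hit, 1])
  sort(unique(p), method = "radix")
}
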