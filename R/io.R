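# Readers/writers for the artifact's external file formats: pair-channel
# TSVs, FI score tables, GCT/TSV expression counts with sample metadata,
# ortholog maps, alias tables, JSONL abstract corpora and the enrichment
# output table.

#' Read a gene-pair channel from a 2- or 3-column TSV
#'
#' Columns: geneA, geneB and an optional score; when a score column is
#' present, rows with score below `minScore` are dropped before
#' canonicalisation.
#'
#' @param path TSV file path (header optional, detected by non-numeric
#'   third column on the first line being absent/numeric).
#' @param name,category Channel identity (see [featureChannel()]).
#' @param minScore Optional score filter applied to a third column.
#' @param header Whether the file has a header line, default FALSE.
#' @return A [FeatureChannel-class].
#' @export
readPairChannel <- function(path, name = basename(path), category = "ppi",
                            minScore = NULL, header = FALSE) {
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("pair file needs at least 2 columns: ", path)
  if (!is.null(minScore)) {
    if (ncol(d) < 3) stop("minScore given but no score column in ", path)
    d <- d[as.numeric(d[[3]]) >= minScore, , drop = FALSE]
  }
  keep <- d[[1]] != d[[2]]
  featureChannel(name, category,
                 if (any(keep)) pairKey(toupper(d[[1]][keep]),
                                        toupper(d[[2]][keep]))
                 else character(0))
}

#' Write / read an FI score table (TSV: geneA, geneB, score)
#' @param scores Named numeric vector (pair key -> score).
#' @param path File path.
#' @return `writeFIScores`: `path` invisibly; `readFIScores`: named numeric
#'   vector.
#' @export
writeFIScores <- function(scores, path) {
  m <- splitPairKey(names(scores))
  utils::write.table(
    data.frame(geneA = m[, 1], geneB = m[, 2], score = unname(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFIScores
#' @export
readFIScores <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$score), pairKey(d$geneA, d$geneB))
}

#' Read an expression count matrix with sample metadata
#'
#' Accepts strict TSV (gene id column + one column per sample) or a
#' GCT-like dialect (leading `#1.2` version line, dimensions line, and a
#' second `Description` annotation column, all tolerated and skipped). The
#' metadata TSV must provide columns `sample_id`, `rin`, `group`.
#'
#' @param countsPath Counts matrix path.
#' @param metaPath Optional sample metadata path.
#' @return A [SummarizedExperiment::SummarizedExperiment]
#'   (see [expressionSE()]).
#' @export
readExpressionMatrix <- function(countsPath, metaPath = NULL) {
  first <- readLines(countsPath, n = 1)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  d <- utils::read.delim(countsPath, skip = skip, check.names = FALSE,
                         stringsAsFactors = FALSE)
  rn <- as.character(d[[1]])
  d[[1]] <- NULL
  if (ncol(d) > 0 && !is.numeric(d[[1]])) d[[1]] <- NULL  # Description col
  counts <- as.matrix(d)
  rownames(counts) <- toupper(rn)
  rin <- rep(NA_real_, ncol(counts))
  group <- rep("all", ncol(counts))
  if (!is.null(metaPath)) {
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    idx <- match(colnames(counts), meta$sample_id)
    rin <- meta$rin[idx]
    group <- meta$group[idx]
  }
  expressionSE(counts, rin = rin, group = group)
}

#' Write an expression SummarizedExperiment as counts + metadata TSVs
#' @param se Expression SummarizedExperiment.
#' @param countsPath,metaPath Output paths.
#' @return `countsPath`, invisibly.
#' @export
writeExpressionMatrix <- function(se, countsPath, metaPath) {
  counts <- SummarizedExperiment::assay(se, "counts")
  utils::write.table(
    data.frame(gene = rownames(counts), counts, check.names = FALSE),
    countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(se)
  utils::write.table(
    data.frame(sample_id = rownames(cd), rin = cd$rin, group = cd$group),
    metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(countsPath)
}

#' Read an ortholog map (2-column TSV: source_gene, human_symbol)
#' @param path TSV path.
#' @return Named list source gene -> character vector of human symbols.
#' @export
readOrthologMap <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  split(toupper(d[[2]]), as.character(d[[1]]))
}

#' Read a gene alias table (TSV: symbol, alias)
#' @param path TSV path.
#' @return data.frame `symbol`, `alias`.
#' @export
readAliasTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "alias") %in% colnames(d)))
    stop("alias table needs columns symbol, alias")
  d
}

#' Read / write an abstract corpus as JSONL ({"pmid":..., "text":...})
#' @param path JSONL path.
#' @return `readCorpusJSONL`: data.frame `pmid`, `text`.
#' @export
readCorpusJSONL <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(pmid = vapply(recs, function(r) as.character(r$pmid), character(1)),
             text = vapply(recs, function(r) as.character(r$text), character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname readCorpusJSONL
#' @param corpus data.frame `pmid`, `text`.
#' @export
writeCorpusJSONL <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i)
    as.character(jsonlite::toJSON(list(pmid = corpus$pmid[i],
                                       text = corpus$text[i]),
                                  auto_unbox = TRUE)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the interacting-pathway record table as TSV
#' @param records data.frame from [interactingPathways()] /
#'   [interactingPathwaysAll()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTSV <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
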