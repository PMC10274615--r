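# Reaction-level pathway data model: JSON load/serialise, gene-set
# derivation and extraction of reference functional interactions.
#
# JSON schema (version 1):
# {
#   "version": 1,
#   "genes":     [{"symbol", "uniprot", "tdl"}],
#   "entities":  [{"id", "kind", "components": [...], "gene"}],
#   "reactions": [{"id", "inputs": [...], "outputs": [...],
#                  "catalysts": [...], "activators": [...],
#                  "inhibitors": [...], "summation"}],
#   "pathways":  [{"id", "name", "children": [...], "summation"}],
#   "top_level": [...]
# }
# kind is one of protein/complex/set/small_molecule; protein entities carry
# "gene" and no components; children reference pathway or reaction ids; the
# pathway hierarchy must be a DAG.

chr0 <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))
str1 <- function(x, default = NA_character_) {
  if (is.null(x) || length(x) == 0) default else as.character(x)[1]
}

#' Construct a PathwayDatabase from component records
#'
#' Low-level constructor used by [loadPathwayDb()] and the synthetic
#' generators; validates all invariants (reference resolution, role
#' disjointness, DAG hierarchy).
#'
#' @param genes data.frame with columns `symbol`, `uniprot`, `tdl`.
#' @param entities,reactions,pathways lists of records (see class docs).
#' @param topLevel character vector of top-level pathway ids.
#' @return A validated [PathwayDatabase-class].
#' @export
newPathwayDatabase <- function(genes, entities, reactions, pathways, topLevel) {
  if (is.null(genes) || nrow(genes) == 0) {
    genes <- data.frame(symbol = character(0), uniprot = character(0),
                        tdl = character(0), stringsAsFactors = FALSE)
  }
  genes$symbol <- toupper(genes$symbol)
  names(entities) <- vapply(entities, function(e) e$id, character(1))
  names(reactions) <- vapply(reactions, function(r) r$id, character(1))
  names(pathways) <- vapply(pathways, function(p) p$id, character(1))
  new("PathwayDatabase", genes = genes, entities = entities,
      reactions = reactions, pathways = pathways,
      topLevel = as.character(topLevel))
}

#' Load a pathway database from its JSON document
#'
#' @param path Path to a pathway-JSON file (schema above).
#' @return A validated [PathwayDatabase-class]. Gene symbols are uppercased
#'   at load. Load -> serialise ([writePathwayDb()]) -> load is the identity
#'   on content.
#' @export
loadPathwayDb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  genes <- if (length(doc$genes)) {
    data.frame(
      symbol = vapply(doc$genes, function(g) toupper(str1(g$symbol, "")), character(1)),
      uniprot = vapply(doc$genes, function(g) str1(g$uniprot), character(1)),
      tdl = vapply(doc$genes, function(g) str1(g$tdl, "unknown"), character(1)),
      stringsAsFactors = FALSE
    )
  } else NULL
  entities <- lapply(doc$entities, function(e) list(
    id = str1(e$id), kind = str1(e$kind),
    components = chr0(e$components), gene = str1(e$gene)
  ))
  reactions <- lapply(doc$reactions, function(r) list(
    id = str1(r$id), inputs = chr0(r$inputs), outputs = chr0(r$outputs),
    catalysts = chr0(r$catalysts), activators = chr0(r$activators),
    inhibitors = chr0(r$inhibitors), summation = str1(r$summation)
  ))
  pathways <- lapply(doc$pathways, function(p) list(
    id = str1(p$id), name = str1(p$name, str1(p$id)),
    children = chr0(p$children), summation = str1(p$summation)
  ))
  newPathwayDatabase(genes, entities, reactions, pathways, chr0(doc$top_level))
}

#' Serialise a PathwayDatabase back to its JSON document
#' @param db A [PathwayDatabase-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePathwayDb <- function(db, path) {
  dropNA <- function(x) lapply(x, function(v) {
    if (length(v) == 1 && is.na(v)) NULL else v
  })
  doc <- list(
    version = 1L,
    genes = lapply(seq_len(nrow(db@genes)), function(i) dropNA(list(
      symbol = db@genes$symbol[i], uniprot = db@genes$uniprot[i],
      tdl = db@genes$tdl[i]
    ))),
    entities = lapply(unname(db@entities), dropNA),
    reactions = lapply(unname(db@reactions), dropNA),
    pathways = lapply(unname(db@pathways), dropNA),
    top_level = db@topLevel
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

# genes of one entity, flattening nested complexes/sets
entityGenes <- function(db, entityId, seen = character(0)) {
  e <- db@entities[[entityId]]
  if (is.null(e)) stop("unknown entity id: ", entityId)
  if (entityId %in% seen) return(character(0))  # guard against cyclic nesting
  switch(e$kind,
    protein = e$gene,
    complex = ,
    set = unique(unlist(lapply(e$components, entityGenes, db = db,
                               seen = c(seen, entityId)))),
    character(0)
  )
}

reactionEntityIds <- function(r) {
  unique(c(r$inputs, r$outputs, r$catalysts, r$activators, r$inhibitors))
}

# all reaction ids under an event (pathway or reaction), recursively
eventReactions <- function(db, eventId) {
  if (eventId %in% names(db@reactions)) return(eventId)
  p <- db@pathways[[eventId]]
  if (is.null(p)) stop("unknown event id: ", eventId)
  unique(unlist(lapply(p$children, eventReactions, db = db)))
}

#' Gene set of an event
#'
#' The union of gene symbols of all protein entities reachable through the
#' event's descendant reactions, flattening complex and set membership
#' recursively. Genes propagate up the hierarchy: a parent's gene set
#' contains every child's.
#'
#' @param db A [PathwayDatabase-class].
#' @param eventId A pathway or reaction id.
#' @return Sorted character vector of gene symbols.
#' @export
eventGeneSet <- function(db, eventId) {
  rids <- eventReactions(db, eventId)
  genes <- unlist(lapply(rids, function(rid) {
    r <- db@reactions[[rid]]
    unlist(lapply(reactionEntityIds(r), entityGenes, db = db))
  }))
  if (is.null(genes)) return(character(0))
  sort(unique(genes), method = "radix")
}

#' Gene sets for all pathways
#' @param db A [PathwayDatabase-class].
#' @param ids Pathway ids (default: all).
#' @return Named list of sorted gene-symbol vectors.
#' @export
pathwayGeneSets <- function(db, ids = pathwayIds(db)) {
  stats::setNames(lapply(ids, eventGeneSet, db = db), ids)
}

#' Extract reference functional interactions from complexes and reactions
#'
#' Reference FIs are the classifier's positive examples. A pair is emitted
#' for (i) every two distinct protein components of a common complex
#' (flattening nested complexes/sets), (ii) every input-protein /
#' catalyst-protein pair of a reaction, and (iii) every pair of distinct
#' input proteins of a reaction. Regulator-derived pairs are off by default
#' because regulation edges are directional while the FI set is undirected.
#'
#' @param db A [PathwayDatabase-class].
#' @param includeRegulators Also emit (activator/inhibitor protein, input
#'   protein) pairs. Default `FALSE`.
#' @return Sorted character vector of canonical pair keys (no self-pairs,
#'   each unordered pair once).
#' @export
extractReferenceFIs <- function(db, includeRegulators = FALSE) {
  pairsOf <- function(genes) {
    genes <- unique(genes)
    if (length(genes) < 2) return(character(0))
    idx <- utils::combn(length(genes), 2)
    pairKey(genes[idx[1, ]], genes[idx[2, ]])
  }
  crossOf <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) || !length(b)) return(character(0))
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, , drop = FALSE]
    if (!nrow(g)) return(character(0))
    pairKey(g$a, g$b)
  }
  out <- character(0)
  for (e in db@entities) {
    if (e$kind == "complex") out <- c(out, pairsOf(entityGenes(db, e$id)))
  }
  for (r in db@reactions) {
    ig <- unique(unlist(lapply(r$inputs, entityGenes, db = db)))
    cg <- unique(unlist(lapply(r$catalysts, entityGenes, db = db)))
    out <- c(out, pairsOf(ig), crossOf(ig, cg))
    if (includeRegulators) {
      rg <- unique(unlist(lapply(c(r$activators, r$inhibitors),
                                 entityGenes, db = db)))
      out <- c(out, crossOf(ig, rg))
    }
  }
  sort(unique(out), method = "radix")
}

#' Export pathway gene sets in GMT format
#'
#' One tab-separated line per pathway: name, id, then the pathway's gene
#' symbols from [eventGeneSet()].
#'
#' @param db A [PathwayDatabase-class].
#' @param path Output file path.
#' @param ids Pathway ids to export (default: all).
#' @return `path`, invisibly.
#' @export
exportGMT <- function(db, path, ids = pathwayIds(db)) {
  lines <- vapply(ids, function(id) {
    paste(c(pathwayName(db, id), id, eventGeneSet(db, id)), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}
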