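#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' PathwayDatabase: a reaction-level pathway knowledgebase
#'
#' Holds a hierarchical event model mirroring curated pathway databases:
#' pathways contain child events (sub-pathways or reactions); reactions
#' connect physical entities (proteins, complexes, sets, small molecules)
#' through input/output/catalyst/activator/inhibitor roles; protein entities
#' map to genes carrying a target-development level (Tdark/Tbio/Tchem/Tclin).
#'
#' @slot genes data.frame with columns `symbol`, `uniprot`, `tdl`.
#' @slot entities named list of entity records
#'   (`id`, `kind`, `components`, `gene`).
#' @slot reactions named list of reaction records (`id`, `inputs`, `outputs`,
#'   `catalysts`, `activators`, `inhibitors`, `summation`).
#' @slot pathways named list of pathway records
#'   (`id`, `name`, `children`, `summation`).
#' @slot topLevel character vector of top-level pathway ids.
#' @export
setClass("PathwayDatabase",
  representation(
    genes = "data.frame",
    entities = "list",
    reactions = "list",
    pathways = "list",
    topLevel = "character"
  )
)

#' FeatureChannel: one binary gene-pair feature
#'
#' A named set of canonical gene pairs, e.g. one tissue's top co-expression
#' pairs, one organism's orthology-mapped PPIs, a domain-interaction set or a
#' GO biological-process sharing set. Channels are binary: a pair is either
#' a member or not.
#'
#' @slot name channel name.
#' @slot category one of `coexpression`, `ppi`, `similarity`, `domain`,
#'   `gobp`.
#' @slot pairs character vector of canonical pair keys.
#' @slot meta free-form list (e.g. ortholog-mapping drop counts).
#' @export
setClass("FeatureChannel",
  representation(
    name = "character",
    category = "character",
    pairs = "character",
    meta = "list"
  ),
  prototype(meta = list())
)

#' FeatureMatrix: gene pairs x binary feature channels
#'
#' @slot pairIndex character vector of canonical pair keys (row order).
#' @slot channels character vector of channel names (column order).
#' @slot values integer matrix in \{0,1\}, `length(pairIndex)` rows.
#' @slot labels optional integer FI labels (1/0), length 0 or nrow.
#' @export
setClass("FeatureMatrix",
  representation(
    pairIndex = "character",
    channels = "character",
    values = "matrix",
    labels = "integerOrNULL"
  ),
  prototype(labels = NULL)
)

#' TrainingSet: labelled pairs for the FI classifier
#'
#' @slot featureMatrix a [FeatureMatrix-class] with labels set.
#' @slot positives canonical pair keys of reference FIs.
#' @slot negatives canonical pair keys of sampled random pairs.
#' @slot seed integer seed used for negative sampling.
#' @export
setClass("TrainingSet",
  representation(
    featureMatrix = "FeatureMatrix",
    positives = "character",
    negatives = "character",
    seed = "integer"
  )
)

#' FIClassifier: a trained functional-interaction classifier
#'
#' Wraps a probability random forest together with the channel names it was
#' trained on; prediction refuses feature matrices whose channels do not
#' match by name and order.
#'
#' @slot model the underlying fitted ensemble (a `ranger` object).
#' @slot channels channel names, in training column order.
#' @slot config the [classifierConfig()] list used for training.
#' @export
setClass("FIClassifier",
  representation(
    model = "ANY",
    channels = "character",
    config = "list"
  )
)

#' BooleanNetwork: fuzzy-logic network compiled from one pathway
#'
#' Bipartite graph of activity-bearing entity nodes (activities in `[0,1]`)
#' and reaction transfer nodes; edges carry the reaction role.
#'
#' @slot entityNodes character vector of entity node ids (sorted).
#' @slot reactionNodes character vector of reaction node ids (sorted).
#' @slot edges data.frame with columns `source`, `target`, `role`
#'   (role in input/output/catalyst/activator/inhibitor).
#' @slot hillK Hill half-saturation constant.
#' @slot hillN Hill exponent.
#' @slot entityGene named character: gene symbol for protein entity nodes.
#' @export
setClass("BooleanNetwork",
  representation(
    entityNodes = "character",
    reactionNodes = "character",
    edges = "data.frame",
    hillK = "numeric",
    hillN = "numeric",
    entityGene = "character"
  )
)

## ---- validity ----

validPathwayDatabase <- function(object) {
  msgs <- character(0)
  g <- object@genes
  if (nrow(g) > 0) {
    if (anyDuplicated(g$symbol)) msgs <- c(msgs, "duplicated gene symbols")
    if (any(!nzchar(g$symbol))) msgs <- c(msgs, "empty gene symbol")
    if (any(g$symbol != toupper(g$symbol)))
      msgs <- c(msgs, "gene symbols must be uppercase (canonical form)")
    bad <- setdiff(unique(g$tdl), c("Tdark", "Tbio", "Tchem", "Tclin", "unknown"))
    if (length(bad)) msgs <- c(msgs, paste("invalid tdl:", paste(bad, collapse = ",")))
  }
  eids <- names(object@entities)
  rids <- names(object@reactions)
  pids <- names(object@pathways)
  if (anyDuplicated(eids)) msgs <- c(msgs, "duplicated entity ids")
  if (anyDuplicated(rids)) msgs <- c(msgs, "duplicated reaction ids")
  if (anyDuplicated(pids)) msgs <- c(msgs, "duplicated pathway ids")
  if (anyDuplicated(c(eids, rids, pids)))
    msgs <- c(msgs, "ids not unique across entities/reactions/pathways")
  for (e in object@entities) {
    if (e$kind == "protein") {
      if (is.null(e$gene) || !nzchar(e$gene) || !(e$gene %in% g$symbol))
        msgs <- c(msgs, paste0("protein entity ", e$id, " has unknown gene"))
      if (length(e$components))
        msgs <- c(msgs, paste0("protein entity ", e$id, " has components"))
    }
    if (e$kind %in% c("complex", "set")) {
      if (length(e$components) < 1)
        msgs <- c(msgs, paste0(e$kind, " entity ", e$id, " has no components"))
      missing <- setdiff(e$components, eids)
      if (length(missing))
        msgs <- c(msgs, paste0("entity ", e$id, " references missing entity id ",
                               paste(missing, collapse = ",")))
    }
  }
  for (r in object@reactions) {
    if (length(r$inputs) < 1 || length(r$outputs) < 1)
      msgs <- c(msgs, paste0("reaction ", r$id, " must have >=1 input and output"))
    roles <- list(r$inputs, r$outputs, r$catalysts, r$activators, r$inhibitors)
    refs <- unlist(roles)
    missing <- setdiff(refs, eids)
    if (length(missing))
      msgs <- c(msgs, paste0("reaction ", r$id, " references missing entity id ",
                             paste(missing, collapse = ",")))
    if (anyDuplicated(refs))
      msgs <- c(msgs, paste0("reaction ", r$id, " role lists are not disjoint"))
  }
  for (p in object@pathways) {
    missing <- setdiff(p$children, c(pids, rids))
    if (length(missing))
      msgs <- c(msgs, paste0("pathway ", p$id, " references missing event id ",
                             paste(missing, collapse = ",")))
  }
  missingTop <- setdiff(object@topLevel, pids)
  if (length(missingTop))
    msgs <- c(msgs, paste0("top_level references missing pathway id ",
                           paste(missingTop, collapse = ",")))
  cyc <- findPathwayCycle(object)
  if (!is.null(cyc))
    msgs <- c(msgs, paste0("cycle in event hierarchy: ", paste(cyc, collapse = " -> ")))
  if (length(msgs)) msgs else TRUE
}

setValidity("PathwayDatabase", validPathwayDatabase)

# DFS cycle detection over pathway children; returns the cycle or NULL
findPathwayCycle <- function(db) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  cycle <- NULL
  visit <- function(id, stack) {
    st <- mget(id, envir = state, ifnotfound = list(0L))[[1]]
    if (st == 1L) {
      cycle <<- c(stack[which(stack == id)[1]:length(stack)], id)
      return(TRUE)
    }
    if (st == 2L) return(FALSE)
    assign(id, 1L, envir = state)
    p <- db@pathways[[id]]
    for (ch in p$children) {
      if (ch %in% names(db@pathways) && visit(ch, c(stack, id))) return(TRUE)
    }
    assign(id, 2L, envir = state)
    FALSE
  }
  for (id in names(db@pathways)) {
    if (visit(id, character(0))) return(cycle)
  }
  NULL
}

setValidity("FeatureChannel", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1 || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  if (!(object@category %in% c("coexpression", "ppi", "similarity", "domain", "gobp")))
    msgs <- c(msgs, "invalid category")
  if (length(object@pairs)) {
    if (anyDuplicated(object@pairs)) msgs <- c(msgs, "duplicated pairs")
    m <- splitPairKey(object@pairs)
    if (any(m[, 1] == m[, 2])) msgs <- c(msgs, "self-pairs present")
    if (!identical(object@pairs, pairKey(m[, 1], m[, 2])))
      msgs <- c(msgs, "pairs are not canonical")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("FeatureMatrix", function(object) {
  msgs <- character(0)
  if (nrow(object@values) != length(object@pairIndex))
    msgs <- c(msgs, "row count != pair index length")
  if (ncol(object@values) != length(object@channels))
    msgs <- c(msgs, "column count != channel count")
  if (anyDuplicated(object@channels)) msgs <- c(msgs, "duplicated channel names")
  if (length(object@values) && !all(object@values %in% c(0L, 1L)))
    msgs <- c(msgs, "values must be binary 0/1")
  if (!is.null(object@labels)) {
    if (length(object@labels) != length(object@pairIndex))
      msgs <- c(msgs, "labels length != pair count")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be 0/1")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("TrainingSet", function(object) {
  msgs <- character(0)
  if (length(intersect(object@positives, object@negatives)))
    msgs <- c(msgs, "positives and negatives overlap")
  fm <- object@featureMatrix
  if (is.null(fm@labels)) {
    msgs <- c(msgs, "feature matrix must carry labels")
  } else {
    want <- ifelse(fm@pairIndex %in% object@positives, 1L, 0L)
    if (!identical(fm@labels, want))
      msgs <- c(msgs, "labels inconsistent with positive/negative sets")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("BooleanNetwork", function(object) {
  msgs <- character(0)
  ed <- object@edges
  if (!all(c("source", "target", "role") %in% colnames(ed)))
    msgs <- c(msgs, "edges need source/target/role columns")
  if (object@hillK <= 0) msgs <- c(msgs, "hillK must be > 0")
  if (object@hillN < 1) msgs <- c(msgs, "hillN must be >= 1")
  for (r in object@reactionNodes) {
    nin <- sum(ed$target == r & ed$role %in% c("input", "catalyst", "activator"))
    nout <- sum(ed$source == r & ed$role == "output")
    if (nin < 1 || nout < 1)
      msgs <- c(msgs, paste0("reaction node ", r, " lacks input or output edges"))
  }
  if (length(msgs)) msgs else TRUE
})

## ---- show methods ----

setMethod("show", "PathwayDatabase", function(object) {
  cat("PathwayDatabase with", nrow(object@genes), "genes,",
      length(object@entities), "entities,",
      length(object@reactions), "reactions,",
      length(object@pathways), "pathways (",
      length(object@topLevel), "top-level )\n")
  nd <- sum(object@genes$tdl == "Tdark")
  if (nrow(object@genes)) cat("  Tdark genes:", nd, "\n")
})

setMethod("show", "FeatureChannel", function(object) {
  cat("FeatureChannel", sQuote(object@name), "[", object@category, "]:",
      length(object@pairs), "pairs\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", length(object@pairIndex), "pairs x",
      length(object@channels), "channels",
      if (!is.null(object@labels)) sprintf("(labelled, %d positives)",
                                           sum(object@labels)) else "", "\n")
})

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", length(object@positives), "positives,",
      length(object@negatives), "negatives (seed", object@seed, ")\n")
})

setMethod("show", "FIClassifier", function(object) {
  cat("FIClassifier over", length(object@channels), "channels:",
      paste(utils::head(object@channels, 5), collapse = ", "),
      if (length(object@channels) > 5) "..." else "", "\n")
})

setMethod("show", "BooleanNetwork", function(object) {
  cat("BooleanNetwork:", length(object@entityNodes), "entity nodes,",
      length(object@reactionNodes), "reaction nodes,",
      nrow(object@edges), "edges; Hill(K =", object@hillK,
      ", n =", object@hillN, ")\n")
})

## ---- accessors ----

#' @describeIn PathwayDatabase-class Gene table accessor.
#' @param db A `PathwayDatabase`.
#' @export
dbGenes <- function(db) db@genes

#' @describeIn PathwayDatabase-class Gene symbols in the database.
#' @export
dbGeneSymbols <- function(db) db@genes$symbol

#' @describeIn PathwayDatabase-class Pathway ids.
#' @export
pathwayIds <- function(db) names(db@pathways)

#' @describeIn PathwayDatabase-class Pathway display name.
#' @param pathwayId Pathway id.
#' @export
pathwayName <- function(db, pathwayId) {
  p <- db@pathways[[pathwayId]]
  if (is.null(p)) stop("unknown pathway id: ", pathwayId)
  p$name
}

#' Accessors for FeatureMatrix
#' @param fm A [FeatureMatrix-class].
#' @return `pairIndex`: character pair keys; `channelNames`: character;
#'   `featureValues`: binary integer matrix; `fiLabels`: integer or NULL.
#' @export
pairIndex <- function(fm) fm@pairIndex

#' @rdname pairIndex
#' @export
channelNames <- function(fm) fm@channels

#' @rdname pairIndex
#' @export
featureValues <- function(fm) {
  v <- fm@values
  dimnames(v) <- list(fm@pairIndex, fm@channels)
  v
}

#' @rdname pairIndex
#' @export
fiLabels <- function(fm) fm@labels

#' @describeIn FeatureChannel-class Pair membership accessor.
#' @param channel A `FeatureChannel`.
#' @export
channelPairs <- function(channel) channel@pairs
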