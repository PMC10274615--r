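# Fuzzy-logic Boolean-network simulation of pathways: compile a pathway's
# reactions into a bipartite entity/reaction network, run synchronous
# discrete-time simulations with a Hill transfer function, and score a
# gene's impact on a pathway as the trapezoidal AUC difference between
# perturbed and baseline time courses, averaged over reaction outputs.
#
# Update semantics (declared convention, configurable through hillK/hillN,
# steps, tol and the initial activities):
#  - reaction firing = fuzzy-AND (min) over Hill-transformed activities of
#    inputs and catalysts, multiplied by prod(1 - hill(inhibitor)) over
#    inhibitors, fuzzy-OR (max) combined with hill(activator) contributions;
#  - produced entity activity = fuzzy-OR (max) over firing levels of its
#    producing reactions;
#  - source entities (no producing reaction) hold their initial value;
#  - perturbation, applied every step: activation max-combines the injected
#    FI strength s with the target's computed activity; inhibition
#    multiplies it by (1 - s). Both keep activities in [0,1] and make s = 0
#    the exact null.

#' Hill transfer function
#'
#' The sigmoidal activation curve `x^n / (K^n + x^n)` used by the fuzzy
#' logic; `hill(K) = 0.5` (half-saturation), `hill(0) = 0`.
#'
#' @param x Activity in `[0,1]` (vectorised).
#' @param K Half-saturation constant, > 0. Default 0.5.
#' @param n Hill exponent, >= 1. Default 4 (a symmetric sigmoid).
#' @return Values in `[0,1]`.
#' @export
hill <- function(x, K = 0.5, n = 4) {
  if (any(x < 0) || any(x > 1)) stop("activity x must lie in [0,1]")
  if (K <= 0) stop("K must be > 0")
  if (n < 1) stop("n must be >= 1")
  x^n / (K^n + x^n)
}

#' Construct a BooleanNetwork directly from node and edge lists
#'
#' Used by [pathwayToNetwork()] and by tests that build random networks.
#'
#' @param entityNodes,reactionNodes Character node ids.
#' @param edges data.frame with columns `source`, `target`, `role` (role in
#'   input/output/catalyst/activator/inhibitor; input/catalyst/activator/
#'   inhibitor edges run entity -> reaction, output edges reaction ->
#'   entity).
#' @param hillK,hillN Hill parameters (defaults 0.5 and 4).
#' @param entityGene Optional named character mapping protein entity nodes
#'   to gene symbols.
#' @return A validated [BooleanNetwork-class].
#' @export
booleanNetwork <- function(entityNodes, reactionNodes, edges,
                           hillK = 0.5, hillN = 4,
                           entityGene = character(0)) {
  new("BooleanNetwork",
      entityNodes = sort(as.character(entityNodes), method = "radix"),
      reactionNodes = sort(as.character(reactionNodes), method = "radix"),
      edges = edges, hillK = hillK, hillN = hillN,
      entityGene = entityGene)
}

#' Compile one pathway into a fuzzy-logic Boolean network
#'
#' One activity-bearing node per physical entity participating in the
#' pathway's reactions (complexes and small molecules are nodes of their
#' own, not flattened) and one transfer node per reaction; edges preserve
#' the reaction roles. Node ordering is deterministic (radix-sorted ids).
#'
#' @param db A [PathwayDatabase-class].
#' @param pathwayId Pathway id; must contain at least one reaction.
#' @param hillK,hillN Hill parameters, defaults 0.5 and 4.
#' @return A [BooleanNetwork-class].
#' @export
pathwayToNetwork <- function(db, pathwayId, hillK = 0.5, hillN = 4) {
  rids <- eventReactions(db, pathwayId)
  if (length(rids) == 0) stop("pathway ", pathwayId, " has no reactions")
  rids <- sort(rids, method = "radix")
  edges <- list()
  ents <- character(0)
  for (rid in rids) {
    r <- db@reactions[[rid]]
    ents <- c(ents, reactionEntityIds(r))
    add <- function(from, role) {
      if (length(from))
        data.frame(source = from, target = rid, role = role,
                   stringsAsFactors = FALSE)
    }
    edges[[length(edges) + 1L]] <- add(r$inputs, "input")
    edges[[length(edges) + 1L]] <- add(r$catalysts, "catalyst")
    edges[[length(edges) + 1L]] <- add(r$activators, "activator")
    edges[[length(edges) + 1L]] <- add(r$inhibitors, "inhibitor")
    edges[[length(edges) + 1L]] <- data.frame(
      source = rid, target = r$outputs, role = "output",
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  ents <- sort(unique(ents), method = "radix")
  eg <- vapply(ents, function(id) {
    e <- db@entities[[id]]
    if (!is.null(e) && e$kind == "protein") e$gene else NA_character_
  }, character(1))
  booleanNetwork(ents, rids, edges, hillK = hillK, hillN = hillN,
                 entityGene = eg[!is.na(eg)])
}

#' Define a perturbation for the simulator
#'
#' @param mode `"none"`, `"activation"` or `"inhibition"`.
#' @param targets Named numeric vector: entity node -> injection strength in
#'   `[0,1]` (the FI prediction score).
#' @return A classed list.
#' @export
perturbation <- function(mode = c("none", "activation", "inhibition"),
                         targets = numeric(0)) {
  mode <- match.arg(mode)
  if (length(targets) && (any(targets < 0) || any(targets > 1)))
    stop("perturbation strengths must lie in [0,1]")
  structure(list(mode = mode, targets = targets), class = "Perturbation")
}

# reaction role lists and producer map, precompiled once per simulation
compileNetwork <- function(net) {
  ed <- net@edges
  roleOf <- function(rid, role) ed$source[ed$target == rid & ed$role == role]
  reactions <- lapply(net@reactionNodes, function(rid) list(
    inputs = roleOf(rid, "input"), catalysts = roleOf(rid, "catalyst"),
    activators = roleOf(rid, "activator"),
    inhibitors = roleOf(rid, "inhibitor"),
    outputs = ed$target[ed$source == rid & ed$role == "output"]
  ))
  names(reactions) <- net@reactionNodes
  producedBy <- lapply(net@entityNodes, function(en)
    ed$source[ed$target == en & ed$role == "output"])
  names(producedBy) <- net@entityNodes
  list(reactions = reactions, producedBy = producedBy)
}

#' Output entity nodes of a network
#'
#' The deduplicated set of entity nodes appearing as the output of at least
#' one reaction: the averaging denominator of the simulation scores.
#' @param net A [BooleanNetwork-class].
#' @return Character vector of entity node ids.
#' @export
outputNodes <- function(net) {
  ed <- net@edges
  sort(unique(ed$target[ed$role == "output"]), method = "radix")
}

#' Default initial activities
#'
#' Source entities (no producing reaction) start at `sourceValue` (default
#' 1.0) and are clamped there; produced entities start at 0.
#' @param net A [BooleanNetwork-class].
#' @param sourceValue Initial activity of source entities.
#' @return Named numeric vector over entity nodes.
#' @export
defaultInit <- function(net, sourceValue = 1.0) {
  comp <- compileNetwork(net)
  src <- vapply(net@entityNodes, function(en)
    length(comp$producedBy[[en]]) == 0, logical(1))
  stats::setNames(ifelse(src, sourceValue, 0), net@entityNodes)
}

#' Run a synchronous fuzzy-logic simulation
#'
#' Synchronous discrete-time updates (semantics above) for at most `steps`
#' steps, stopping early when the maximum absolute node change drops below
#' `tol` (the `converged` flag records which). The perturbation is applied
#' at every step.
#'
#' @param net A [BooleanNetwork-class].
#' @param init Named numeric initial activities over entity nodes; default
#'   [defaultInit()].
#' @param steps Maximum number of steps, default 100.
#' @param tol Convergence tolerance on the max node change, default 1e-6;
#'   use 0 to force a fixed-length trace.
#' @param pert A [perturbation()]; default none.
#' @return A `SimulationTrace`: list with `trace` (a `(T+1) x nodes`
#'   activity matrix, row 0 = initial state), `steps` (T) and `converged`.
#' @export
simulateNetwork <- function(net, init = NULL, steps = 100L, tol = 1e-6,
                            pert = perturbation("none")) {
  comp <- compileNetwork(net)
  ents <- net@entityNodes
  if (is.null(init)) init <- defaultInit(net)
  if (!all(ents %in% names(init))) stop("init must cover all entity nodes")
  act <- init[ents]
  if (any(act < 0) || any(act > 1)) stop("initial activities must lie in [0,1]")
  badTargets <- setdiff(names(pert$targets), ents)
  if (length(badTargets))
    stop("perturbation targets not in network: ",
         paste(badTargets, collapse = ","))
  isSource <- vapply(ents, function(en)
    length(comp$producedBy[[en]]) == 0, logical(1))
  trace <- matrix(NA_real_, nrow = steps + 1L, ncol = length(ents),
                  dimnames = list(NULL, ents))
  trace[1, ] <- act
  converged <- FALSE
  t <- 0L
  while (t < steps) {
    h <- hill(act, net@hillK, net@hillN)
    firing <- vapply(comp$reactions, function(r) {
      base <- min(h[c(r$inputs, r$catalysts)])
      if (length(r$inhibitors)) base <- base * prod(1 - h[r$inhibitors])
      if (length(r$activators)) base <- max(base, max(h[r$activators]))
      base
    }, numeric(1))
    nxt <- act
    for (i in seq_along(ents)) {
      if (!isSource[i]) nxt[i] <- max(firing[comp$producedBy[[ents[i]]]])
    }
    if (pert$mode == "activation" && length(pert$targets)) {
      tg <- names(pert$targets)
      nxt[tg] <- pmax(nxt[tg], pert$targets)
    } else if (pert$mode == "inhibition" && length(pert$targets)) {
      tg <- names(pert$targets)
      nxt[tg] <- nxt[tg] * (1 - pert$targets)
    }
    if (any(!is.finite(nxt))) stop("non-finite activity encountered")
    t <- t + 1L
    trace[t + 1L, ] <- nxt
    delta <- max(abs(nxt - act))
    act <- nxt
    if (tol > 0 && delta < tol) { converged <- TRUE; break }
  }
  structure(list(trace = trace[seq_len(t + 1L), , drop = FALSE], steps = t,
                 converged = converged), class = "SimulationTrace")
}

#' AUC-difference impact of a perturbation on one node
#'
#' Trapezoidal area under the node's time course, normalised by the time
#' horizon: `impact = (AUC_perturbed - AUC_baseline) / T`, in `[-1, 1]`.
#'
#' @param baseline,perturbed `SimulationTrace` objects sharing the same
#'   step count and node set.
#' @param node Entity node id.
#' @return Signed impact in `[-1, 1]`.
#' @export
aucImpact <- function(baseline, perturbed, node) {
  if (baseline$steps != perturbed$steps ||
      !identical(colnames(baseline$trace), colnames(perturbed$trace)))
    stop("baseline and perturbed traces do not match (steps or node set)")
  if (!(node %in% colnames(baseline$trace))) stop("unknown node: ", node)
  Tn <- baseline$steps
  if (Tn == 0) return(0)
  tt <- 0:Tn
  (pracma::trapz(tt, perturbed$trace[, node]) -
     pracma::trapz(tt, baseline$trace[, node])) / Tn
}

#' Simulation scores of a gene on a pathway
#'
#' Runs a baseline simulation (no injection) and two perturbed simulations
#' injecting the gene's FI prediction scores onto its partner proteins'
#' entity nodes - once treating every FI as activating, once as inhibiting
#' (the FI mode is not predicted, so both assumptions are scored). The
#' activation/inhibition score is the mean [aucImpact()] over the pathway's
#' reaction-output nodes. All three runs use a fixed `steps`-length horizon
#' so the time courses align.
#'
#' @param gene Gene symbol.
#' @param fiScores Named numeric vector (pair key -> FI score), e.g. from
#'   [predictScores()].
#' @param db A [PathwayDatabase-class].
#' @param pathwayId Pathway id.
#' @param hillK,hillN Hill parameters.
#' @param steps Simulation horizon, default 100.
#' @param initSource Initial activity of source entities, default 1.0
#'   (clamped sources; note an activation injection onto a source already at
#'   1 is a no-op, so impact fixtures typically lower this).
#' @return List with `average_activation`, `average_inhibition` and
#'   `per_output` (data.frame node/activation/inhibition). When no partner
#'   protein appears in the pathway both averages are 0, with a warning.
#' @export
simulationScores <- function(gene, fiScores, db, pathwayId,
                             hillK = 0.5, hillN = 4, steps = 100L,
                             initSource = 1.0) {
  net <- pathwayToNetwork(db, pathwayId, hillK = hillK, hillN = hillN)
  partners <- pairPartners(gene, names(fiScores))
  eg <- net@entityGene
  targets <- numeric(0)
  for (p in intersect(partners, unique(eg))) {
    s <- unname(fiScores[pairKey(gene, p)])
    nodes <- names(eg)[eg == p]
    targets[nodes] <- s
  }
  outs <- outputNodes(net)
  if (length(targets) == 0) {
    warning("gene ", gene, " has no predicted FI partners in pathway ",
            pathwayId)
    per <- data.frame(node = outs, activation = 0, inhibition = 0,
                      stringsAsFactors = FALSE)
    return(list(average_activation = 0, average_inhibition = 0,
                per_output = per))
  }
  init <- defaultInit(net, sourceValue = initSource)
  base <- simulateNetwork(net, init = init, steps = steps, tol = 0)
  actT <- simulateNetwork(net, init = init, steps = steps, tol = 0,
                          pert = perturbation("activation", targets))
  inhT <- simulateNetwork(net, init = init, steps = steps, tol = 0,
                          pert = perturbation("inhibition", targets))
  per <- data.frame(
    node = outs,
    activation = vapply(outs, function(nd) aucImpact(base, actT, nd),
                        numeric(1)),
    inhibition = vapply(outs, function(nd) aucImpact(base, inhT, nd),
                        numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(average_activation = mean(per$activation),
       average_inhibition = mean(per$inhibition),
       per_output = per)
}
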