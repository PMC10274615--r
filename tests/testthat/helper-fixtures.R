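# Shared in-code fixtures: all built programmatically, no files.

# minimal hand-built database: one top pathway P1 -> sub-pathway SP1 ->
# reaction R1 (inputs A + B, catalyst D, output complex of {C}); plus a
# standalone complex CPX {A,B,C} and a second pathway P2 without reactions.
tinyDb <- function() {
  genes <- data.frame(symbol = c("A", "B", "C", "D", "E"),
                      uniprot = NA_character_,
                      tdl = c("Tdark", "Tbio", "Tbio", "Tchem", "unknown"),
                      stringsAsFactors = FALSE)
  ent <- function(id, kind, components = character(0), gene = NA_character_)
    list(id = id, kind = kind, components = components, gene = gene)
  entities <- list(
    ent("E_A", "protein", gene = "A"), ent("E_B", "protein", gene = "B"),
    ent("E_C", "protein", gene = "C"), ent("E_D", "protein", gene = "D"),
    ent("E_E", "protein", gene = "E"),
    ent("CPX_C", "complex", components = "E_C"),
    ent("CPX_ABC", "complex", components = c("E_A", "E_B", "E_C"))
  )
  reactions <- list(list(
    id = "R1", inputs = c("E_A", "E_B"), outputs = "CPX_C",
    catalysts = "E_D", activators = character(0), inhibitors = character(0),
    summation = "toy reaction"))
  pathways <- list(
    list(id = "SP1", name = "Toy sub", children = "R1",
         summation = "toy sub pathway"),
    list(id = "P1", name = "Toy pathway", children = "SP1",
         summation = "toy pathway"),
    list(id = "P2", name = "Empty pathway", children = character(0),
         summation = NA_character_))
  newPathwayDatabase(genes, entities, reactions, pathways, c("P1", "P2"))
}

# linear chain X -> A -> B (X a clamped source) used by the simulator tests
chainDb <- function() {
  genes <- data.frame(symbol = c("X", "A", "B", "G"), uniprot = NA_character_,
                      tdl = "unknown", stringsAsFactors = FALSE)
  ent <- function(s) list(id = paste0("E_", s), kind = "protein",
                          components = character(0), gene = s)
  entities <- lapply(c("X", "A", "B", "G"), ent)
  reactions <- list(
    list(id = "R1", inputs = "E_X", outputs = "E_A",
         catalysts = character(0), activators = character(0),
         inhibitors = character(0), summation = "x to a"),
    list(id = "R2", inputs = "E_A", outputs = "E_B",
         catalysts = character(0), activators = character(0),
         inhibitors = character(0), summation = "a to b"))
  pathways <- list(
    list(id = "PCH", name = "Chain", children = c("R1", "R2"),
         summation = "chain pathway"),
    list(id = "P2N", name = "Two node", children = "R1",
         summation = "two node pathway"))
  newPathwayDatabase(genes, entities, reactions, pathways, c("PCH", "P2N"))
}

# random well-formed Boolean network: nE entities, nR reactions with
# disjoint random roles; used by the boundedness / null-identity properties
randomNetwork <- function(seed, nE = 8, nR = 4) {
  set.seed(seed)
  ents <- sprintf("e%02d", seq_len(nE))
  rxns <- sprintf("r%02d", seq_len(nR))
  edges <- list()
  for (r in rxns) {
    pool <- sample(ents)
    nIn <- sample(1:2, 1)
    nOut <- sample(1:2, 1)
    roles <- c(rep("input", nIn), rep("output", nOut))
    extra <- sample(c("catalyst", "activator", "inhibitor"),
                    sample(0:2, 1))
    roles <- c(roles, extra)
    picked <- pool[seq_along(roles)]
    isOut <- roles == "output"
    edges[[r]] <- rbind(
      data.frame(source = picked[!isOut], target = r, role = roles[!isOut],
                 stringsAsFactors = FALSE),
      data.frame(source = r, target = picked[isOut], role = "output",
                 stringsAsFactors = FALSE))
  }
  booleanNetwork(ents, rxns, do.call(rbind, edges),
                 hillK = runif(1, 0.3, 0.7), hillN = sample(2:6, 1))
}

# fake embedding provider with a fixed text -> vector dictionary
dictProvider <- function(dict) {
  dim <- length(dict[[1]])
  structure(list(dim = dim, embed = function(text) {
    v <- dict[[text]]
    if (is.null(v)) numeric(dim) else v
  }), class = "EmbeddingProvider")
}

# deterministic counts fixture: nS near-constant samples plus one planted
# composition outlier on the last sample
outlierCounts <- function(nS = 50, nG = 20, shift = 32) {
  base <- matrix(100L, nrow = nG, ncol = nS,
                 dimnames = list(sprintf("G%02d", seq_len(nG)),
                                 sprintf("S%02d", seq_len(nS))))
  jitter <- outer(seq_len(nG), seq_len(nS), function(g, s) (g * 7 + s * 3) %% 5)
  counts <- base + jitter
  counts[seq_len(nG %/% 2), nS] <- counts[seq_len(nG %/% 2), nS] * shift
  counts
}
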