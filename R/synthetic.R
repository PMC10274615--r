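# Deterministic synthetic-data generators. They emulate every external
# input of the framework - a reaction-level pathway database, binary
# gene-pair feature channels with planted FI enrichment, a count matrix
# with a planted co-expression module plus QC artefacts, and an abstract
# corpus with planted pathway-literature similarity - so the whole pipeline
# runs and is testable offline. All generators are pure functions of
# (config, seed): same seed, byte-identical output.

#' Configuration for the synthetic-data generators
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package's tests and examples: 200 genes in 5 two-level pathways; six
#' binary feature channels, five informative (odds-ratio targets 150, 60,
#' 40, 25, 15 - mirroring real channels such as GO-BP sharing, whose odds
#' ratios sit far above the 5.0 vetting gate) and one null channel (target
#' 1); a co-expression module at rho = 0.7 over 120 samples with one
#' planted low-RIN sample and one planted PC-outlier sample; and a corpus
#' of 160 abstracts over 20 planted genes, half on-topic for one target
#' pathway.
#'
#' @param nGenes Number of genes, default 200.
#' @param nPathways Number of top-level pathways, default 5.
#' @param pathwaySizeRange Min/max genes per pathway, default c(15, 25).
#' @param channelEnrichment Per-channel odds-ratio targets,
#'   default c(150, 60, 40, 25, 15, 1).
#' @param channelBaseRate Non-FI membership probability, default 0.02.
#' @param coexprModuleRho Latent-factor correlation of the planted
#'   co-expression module, default 0.7.
#' @param nSamples Samples (or cells) in the expression matrix, default 120.
#' @param noiseSd Log-scale expression noise SD, default 1.0.
#' @param nAbstracts Corpus size, default 160.
#' @param onTopicFraction Fraction of each planted gene's abstracts reusing
#'   the target pathway's vocabulary, default 0.5.
#' @param nPlantedGenes Genes with planted abstracts, default 20.
#' @param tdarkFraction Fraction of genes tagged Tdark, default 0.3.
#' @param seed Mandatory integer seed, default 42.
#' @return A classed list of settings.
#' @export
syntheticConfig <- function(nGenes = 200L, nPathways = 5L,
                            pathwaySizeRange = c(15L, 25L),
                            channelEnrichment = c(150, 60, 40, 25, 15, 1),
                            channelBaseRate = 0.02,
                            coexprModuleRho = 0.7, nSamples = 120L,
                            noiseSd = 1.0, nAbstracts = 160L,
                            onTopicFraction = 0.5, nPlantedGenes = 20L,
                            tdarkFraction = 0.3, seed = 42L) {
  cfg <- list(nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
              pathwaySizeRange = as.integer(pathwaySizeRange),
              channelEnrichment = channelEnrichment,
              channelBaseRate = channelBaseRate,
              coexprModuleRho = coexprModuleRho,
              nSamples = as.integer(nSamples), noiseSd = noiseSd,
              nAbstracts = as.integer(nAbstracts),
              onTopicFraction = onTopicFraction,
              nPlantedGenes = as.integer(nPlantedGenes),
              tdarkFraction = tdarkFraction, seed = as.integer(seed))
  stopifnot(cfg$nGenes > 0, cfg$nPathways > 0, cfg$nSamples > 0,
            cfg$nAbstracts > 0, length(cfg$seed) == 1)
  if (cfg$pathwaySizeRange[2] > cfg$nGenes)
    stop("pathway_size exceeds n_genes")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate a toy reaction-level pathway database
#'
#' Two-level hierarchy: each top-level pathway owns a sub-pathway plus
#' direct reactions; reactions chain protein entities through
#' input/output/catalyst/inhibitor roles and each pathway contributes one
#' complex; every event carries a summation built from a pathway-specific
#' vocabulary; a configurable fraction of genes is tagged Tdark.
#'
#' @param cfg A [syntheticConfig()].
#' @return A validated [PathwayDatabase-class].
#' @export
makeToyPathwayDb <- function(cfg = syntheticConfig()) {
  withSeed(cfg$seed, {
    syms <- sprintf("G%03d", seq_len(cfg$nGenes))
    tdl <- ifelse(stats::runif(cfg$nGenes) < cfg$tdarkFraction, "Tdark",
                  sample(c("Tbio", "Tchem", "Tclin"), cfg$nGenes,
                         replace = TRUE))
    genes <- data.frame(symbol = syms,
                        uniprot = sprintf("P%05d", 10000L + seq_len(cfg$nGenes)),
                        tdl = tdl, stringsAsFactors = FALSE)
    entities <- list()
    for (s in syms) {
      id <- paste0("E_", s)
      entities[[id]] <- list(id = id, kind = "protein",
                             components = character(0), gene = s)
    }
    reactions <- list()
    pathways <- list()
    topLevel <- character(0)
    for (i in seq_len(cfg$nPathways)) {
      size <- sample(seq(cfg$pathwaySizeRange[1], cfg$pathwaySizeRange[2]), 1)
      members <- sample(syms, size)
      vocab <- sprintf("pw%dterm%02d", i, 1:10)
      E <- function(idx) paste0("E_", members[idx])
      mkSum <- function(n) paste(sample(vocab, n, replace = TRUE),
                                 collapse = " ")
      # two complexes feed the chain (complex co-membership is a major
      # source of reference FIs, as in curated databases)
      cpx1 <- sprintf("CPX_%d_1", i)
      cpx2 <- sprintf("CPX_%d_2", i)
      entities[[cpx1]] <- list(id = cpx1, kind = "complex",
                               components = E(1:4), gene = NA_character_)
      entities[[cpx2]] <- list(id = cpx2, kind = "complex",
                               components = E(5:8), gene = NA_character_)
      rids <- character(0)
      rid <- sprintf("R_%d_1", i)
      reactions[[rid]] <- list(
        id = rid, inputs = c(cpx1, E(9)), outputs = E(10),
        catalysts = E(11), activators = character(0),
        inhibitors = character(0),
        summation = paste("complex activation reaction", mkSum(4)))
      rids <- c(rids, rid)
      rid <- sprintf("R_%d_2", i)
      reactions[[rid]] <- list(
        id = rid, inputs = c(cpx2, E(12)), outputs = E(13),
        catalysts = character(0), activators = character(0),
        inhibitors = E(14),
        summation = paste("complex conversion reaction", mkSum(4)))
      rids <- c(rids, rid)
      j <- 9L
      while (j + 3L <= size) {
        rid <- sprintf("R_%d_%d", i, j)
        reactions[[rid]] <- list(
          id = rid,
          inputs = E(c(j, j + 1L)),
          outputs = E(j + 2L),
          catalysts = if (j %% 2 == 0) E(j + 3L) else character(0),
          activators = character(0),
          inhibitors = if (j %% 2 == 1) E(j + 3L) else character(0),
          summation = paste("conversion reaction", mkSum(4)))
        rids <- c(rids, rid)
        j <- j + 2L
      }
      spId <- sprintf("SP_%d", i)
      half <- ceiling(length(rids) / 2)
      pathways[[spId]] <- list(
        id = spId, name = sprintf("Sub-module %d", i),
        children = rids[seq_len(half)],
        summation = paste("sub module", i, mkSum(6)))
      pId <- sprintf("P_%d", i)
      pathways[[pId]] <- list(
        id = pId, name = sprintf("Signaling module %d", i),
        children = c(spId, rids[-seq_len(half)]),
        summation = paste("signaling module", i, mkSum(6)))
      topLevel <- c(topLevel, pId)
    }
    newPathwayDatabase(genes, entities, reactions, pathways, topLevel)
  })
}

#' Generate binary feature channels with planted FI enrichment
#'
#' Each channel includes a pair with probability `pFI` when the pair is a
#' reference FI of `db` and `channelBaseRate` otherwise, with `pFI` solved
#' so the channel's odds of membership given FI over non-FI hits the
#' configured odds-ratio target.
#'
#' @param db A [PathwayDatabase-class] (typically from
#'   [makeToyPathwayDb()]).
#' @param cfg A [syntheticConfig()].
#' @return List of [FeatureChannel-class], one per entry of
#'   `cfg$channelEnrichment`.
#' @export
makeFeatureChannels <- function(db, cfg = syntheticConfig()) {
  fis <- extractReferenceFIs(db)
  universe <- allPairKeys(dbGeneSymbols(db))
  isFI <- universe %in% fis
  cats <- c("gobp", "ppi", "coexpression", "similarity", "domain")
  withSeed(cfg$seed + 1L, {
    lapply(seq_along(cfg$channelEnrichment), function(i) {
      target <- cfg$channelEnrichment[i]
      oddsNon <- cfg$channelBaseRate / (1 - cfg$channelBaseRate)
      pFI <- target * oddsNon / (1 + target * oddsNon)
      # an enriched channel must be able to realise its target: require a
      # usable expected positive count (null channels, target <= 1, exempt)
      if (target > 1 && pFI * sum(isFI) < 5)
        stop("infeasible enrichment target ", target,
             " for this universe size")
      prob <- ifelse(isFI, pFI, cfg$channelBaseRate)
      member <- stats::runif(length(universe)) < prob
      featureChannel(sprintf("channel%02d", i),
                     cats[(i - 1L) %% length(cats) + 1L],
                     universe[member],
                     meta = list(targetOR = target))
    })
  })
}

#' Generate a count matrix with a planted co-expression module
#'
#' Poisson-lognormal counts in which the genes of the first top-level
#' pathway share a latent factor with correlation `coexprModuleRho` on the
#' log scale. Includes RIN metadata with one planted low-RIN sample
#' (rin = 5.0, first sample) and one planted principal-component outlier
#' (last sample; half of the genes shifted up 8 log-units, a composition
#' change that survives cpm normalisation). Plant identities are recorded
#' in the object's metadata.
#'
#' @param db A [PathwayDatabase-class].
#' @param cfg A [syntheticConfig()].
#' @return A [SummarizedExperiment::SummarizedExperiment] (see
#'   [expressionSE()]) with metadata `plantedLowRIN`, `plantedOutlier`,
#'   `moduleGenes`.
#' @export
makeExpressionMatrix <- function(db, cfg = syntheticConfig()) {
  genes <- dbGeneSymbols(db)
  module <- eventGeneSet(db, db@topLevel[1])
  withSeed(cfg$seed + 2L, {
    nS <- cfg$nSamples
    nG <- length(genes)
    rho <- cfg$coexprModuleRho
    sigma <- cfg$noiseSd
    z <- stats::rnorm(nS)
    eps <- matrix(stats::rnorm(nG * nS), nrow = nG)
    logLambda <- matrix(log(100), nrow = nG, ncol = nS)
    inMod <- genes %in% module
    logLambda[inMod, ] <- logLambda[inMod, ] +
      sqrt(rho) * sigma * matrix(z, nrow = sum(inMod), ncol = nS,
                                 byrow = TRUE) +
      sqrt(1 - rho) * sigma * eps[inMod, , drop = FALSE]
    logLambda[!inMod, ] <- logLambda[!inMod, ] +
      sigma * eps[!inMod, , drop = FALSE]
    upGenes <- sample(nG, nG %/% 2)
    logLambda[upGenes, nS] <- logLambda[upGenes, nS] + 8
    counts <- matrix(stats::rpois(nG * nS, exp(logLambda)), nrow = nG,
                     dimnames = list(genes, sprintf("S%03d", seq_len(nS))))
    rin <- round(stats::runif(nS, 6.5, 9.5), 1)
    rin[1] <- 5.0
    se <- expressionSE(counts, rin = rin, group = rep("blood", nS))
    S4Vectors::metadata(se) <- list(
      plantedLowRIN = colnames(counts)[1],
      plantedOutlier = colnames(counts)[nS],
      moduleGenes = module)
    se
  })
}

#' Generate an abstract corpus with planted pathway-literature similarity
#'
#' Abstracts mention their planted gene's symbol; on-topic abstracts reuse
#' tokens specific to the target pathway's summations, so the deterministic
#' pseudo-embedder yields a higher cosine similarity to that pathway;
#' off-topic abstracts use neutral filler vocabulary.
#'
#' @param db A [PathwayDatabase-class].
#' @param cfg A [syntheticConfig()].
#' @return List: `corpus` (data.frame pmid/text), `provider` (the
#'   [pseudoEmbedder()]), `aliases` (data.frame symbol/alias),
#'   `targetPathway`, `plantedGenes`.
#' @export
makeAbstractCorpus <- function(db, cfg = syntheticConfig()) {
  target <- db@topLevel[1]
  tokTarget <- unique(tokenizeText(paste(eventSummations(db, target),
                                         collapse = " ")))
  tokOther <- unique(unlist(lapply(setdiff(db@topLevel, target), function(p)
    tokenizeText(paste(eventSummations(db, p), collapse = " ")))))
  vocab <- setdiff(tokTarget, tokOther)
  if (length(vocab) == 0) vocab <- tokTarget
  filler <- sprintf("filler%02d", 1:40)
  planted <- utils::head(sort(dbGeneSymbols(db), method = "radix"),
                         cfg$nPlantedGenes)
  withSeed(cfg$seed + 3L, {
    pmid <- character(0)
    text <- character(0)
    gene <- character(0)
    nPer <- max(1L, cfg$nAbstracts %/% length(planted))
    nOn <- round(cfg$onTopicFraction * nPer)
    counter <- 0L
    for (g in planted) {
      for (j in seq_len(nPer)) {
        counter <- counter + 1L
        onTopic <- j <= nOn
        words <- if (onTopic) {
          sample(vocab, min(8, length(vocab)), replace = TRUE)
        } else {
          sample(filler, 8, replace = TRUE)
        }
        pmid <- c(pmid, sprintf("PM%05d", counter))
        text <- c(text, paste(g, "studies report that",
                              paste(words, collapse = " ")))
        gene <- c(gene, g)
      }
    }
    list(
      corpus = data.frame(pmid = pmid, text = text, gene = gene,
                          stringsAsFactors = FALSE),
      provider = pseudoEmbedder(),
      aliases = data.frame(symbol = planted, alias = planted,
                           stringsAsFactors = FALSE),
      targetPathway = target,
      plantedGenes = planted)
  })
}

#' Generate a pair of score tables with planted per-gene agreement
#'
#' Emulates two interacting-pathway scoring channels (e.g. FI-based vs
#' co-expression-based enrichment scores) whose per-gene score vectors
#' correlate at a planted level: `B = agreement * A + sqrt(1 - agreement^2)
#' * noise` on a common score-like scale. `agreement = 0` gives independent
#' channels.
#'
#' @param nGenes Number of genes, default 200.
#' @param nPathways Pathways per gene, default 20.
#' @param agreement Planted correlation in `[0, 1)`, default 0.6.
#' @param seed Integer seed.
#' @return List of two numeric gene x pathway matrices `a`, `b`.
#' @export
makeAgreementScores <- function(nGenes = 200L, nPathways = 20L,
                                agreement = 0.6, seed = 42L) {
  stopifnot(agreement >= 0, agreement < 1)
  withSeed(seed, {
    dn <- list(sprintf("G%03d", seq_len(nGenes)),
               sprintf("PW%02d", seq_len(nPathways)))
    A <- matrix(stats::rnorm(nGenes * nPathways), nrow = nGenes, dimnames = dn)
    E <- matrix(stats::rnorm(nGenes * nPathways), nrow = nGenes, dimnames = dn)
    B <- agreement * A + sqrt(1 - agreement^2) * E
    list(a = A + 3, b = B + 3)  # shifted to an enrichment-score-like scale
  })
}

#' Run the full synthetic pipeline end-to-end
#'
#' Generates the toy pathway database and feature channels, vets channels
#' by odds ratio, builds the training set, trains and evaluates the FI
#' classifier, predicts scores for every pair of the universe, thresholds
#' them into predicted FIs and computes the per-gene interacting-pathway
#' enrichment table. Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [syntheticConfig()].
#' @param negRatio Negatives per positive for training, default 10 (a
#'   desk-scale universe of ~20,000 pairs cannot supply the 1:100
#'   protocol ratio; see the package vignette).
#' @param cutoff FI score cutoff, default 0.8.
#' @param orThreshold Odds-ratio vetting threshold, default 5.0.
#' @param repeats Evaluation repeats, default 10.
#' @return List with `db`, `channels`, `selection`, `trainingSet`, `model`,
#'   `report`, `scores`, `predictedFIs`, `enrichment`.
#' @export
runSyntheticPipeline <- function(cfg = syntheticConfig(), negRatio = 10L,
                                 cutoff = 0.8, orThreshold = 5.0,
                                 repeats = 10L) {
  db <- makeToyPathwayDb(cfg)
  channels <- makeFeatureChannels(db, cfg)
  fis <- extractReferenceFIs(db)
  universe <- allPairKeys(dbGeneSymbols(db))
  selection <- selectFeatures(channels, fis, universe,
                              threshold = orThreshold)
  kept <- Filter(function(ch) ch@name %in% selection$selected, channels)
  if (length(kept) == 0) stop("no channel survived odds-ratio vetting")
  ts <- buildTrainingSet(fis, dbGeneSymbols(db), kept, negRatio = negRatio,
                         seed = cfg$seed)
  fit <- trainAndEvaluate(ts, classifierConfig(randomState = cfg$seed),
                          repeats = repeats)
  fmAll <- assembleFeatureMatrix(universe, kept)
  scores <- predictScores(fit$model, fmAll)
  predFIs <- thresholdPredictions(scores, cutoff = cutoff)
  enrichment <- if (length(predFIs))
    enrichmentScoreTable(predFIs, db) else NULL
  list(db = db, channels = channels, selection = selection,
       trainingSet = ts, model = fit$model, report = fit$report,
       scores = scores, predictedFIs = predFIs, enrichment = enrichment)
}
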