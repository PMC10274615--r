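test_that("abstract matching is word-bounded with symbol-aware case rules", {
  corpus <- data.frame(
    pmid = c("PM3", "PM1", "PM2", "PM4", "PM5"),
    text = c("TP53 regulates apoptosis",
             "the CATP53X complex",             # alias inside a longer token
             "studies of p53 signalling",
             "Cellular tumor antigen p53 binds DNA",
             "unrelated abstract"),
    stringsAsFactors = FALSE)
  hits <- matchAbstracts(corpus, c("TP53", "p53"))
  expect_identical(hits$pmid, c("PM2", "PM3", "PM4"))   # ordered by pmid
  # all-uppercase aliases are case-sensitive
  expect_identical(nrow(matchAbstracts(
    data.frame(pmid = "X", text = "tp53 lowercase mention"), "TP53")), 0L)
  # multi-word protein names are case-insensitive
  expect_identical(matchAbstracts(corpus, "cellular tumor antigen p53")$pmid,
                   "PM4")
  expect_identical(nrow(matchAbstracts(corpus[0, ], "TP53")), 0L)
  expect_error(matchAbstracts(corpus, character(0)), "empty alias")
})

test_that("event similarity is the mean cosine over the event tree", {
  db <- tinyDb()   # P1 -> SP1 -> R1, all three with summation text
  dict <- list("toy pathway" = c(1, 0, 0), "toy sub pathway" = c(1, 0, 0),
               "toy reaction" = c(1, 0, 0), abs1 = c(1, 0, 0),
               abs2 = c(0, 1, 0))
  pr <- dictProvider(dict)
  expect_equal(eventSimilarity("P1", pr$embed("abs1"), db, pr), 1)
  expect_equal(eventSimilarity("P1", pr$embed("abs2"), db, pr), 0)
  # mixed cosines average arithmetically: {1, 0, 0.5} -> 0.5
  dict2 <- list("toy pathway" = c(1, 0, 0), "toy sub pathway" = c(0, 1, 0),
                "toy reaction" = c(1, 1, 0) / sqrt(2), q = c(1, 0, 0))
  pr2 <- dictProvider(dict2)
  expect_equal(eventSimilarity("P1", pr2$embed("q"), db, pr2),
               mean(c(1, 0, 1 / sqrt(2))))
  # a pathway with no embeddable text errors
  expect_error(eventSimilarity("P2", c(1, 0, 0), db, pr), "no embeddable")
})

test_that("annotation scores equal an explicit-loop brute force", {
  db <- tinyDb()
  set.seed(21)
  nAbs <- 1500
  corpus <- data.frame(
    pmid = sprintf("PM%04d", seq_len(nAbs)),
    text = paste("GENEA mention", sprintf("tok%d", seq_len(nAbs))),
    stringsAsFactors = FALSE)
  pr <- pseudoEmbedder(dim = 32, nBuckets = 256)
  pws <- c("P1", "SP1")
  k <- 1000
  score <- annotationScore("GENEA", "P1", corpus, db, pr,
                           aliases = "GENEA", k = k, pathwaySet = pws)
  # brute force: explicit loops over abstracts and events
  evTexts <- c("toy pathway", "toy sub pathway", "toy reaction")
  evVecs <- lapply(evTexts, pr$embed)
  spTexts <- c("toy sub pathway", "toy reaction")
  spVecs <- lapply(spTexts, pr$embed)
  simTo <- function(vecs, av) mean(vapply(vecs, cosineSim, numeric(1), y = av))
  av <- lapply(corpus$text, pr$embed)
  simP1 <- vapply(av, function(v) simTo(evVecs, v), numeric(1))
  simSP <- vapply(av, function(v) simTo(spVecs, v), numeric(1))
  rankAvg <- (simP1 + simSP) / 2
  ord <- order(-rankAvg, corpus$pmid, method = "radix")
  keep <- ord[seq_len(k)]                      # exactly 1,000 of 1,500 used
  expect_equal(score, mean(simP1[keep]), tolerance = 1e-12)
  # k = 1: the single top-ranked abstract
  score1 <- annotationScore("GENEA", "P1", corpus, db, pr,
                            aliases = "GENEA", k = 1, pathwaySet = pws)
  expect_equal(score1, simP1[ord[1]], tolerance = 1e-12)
  expect_true(score >= -1 && score <= 1)
})

test_that("annotation scoring handles small corpora and missing genes", {
  db <- tinyDb()
  dict <- list("toy pathway" = c(1, 0), "toy sub pathway" = c(1, 0),
               "toy reaction" = c(1, 0),
               "GENEA one" = c(1, 0), "GENEA two" = c(0, 1))
  pr <- dictProvider(dict)
  corpus <- data.frame(pmid = c("PM1", "PM2"),
                       text = c("GENEA one", "GENEA two"),
                       stringsAsFactors = FALSE)
  # two matched abstracts with similarities {1, 0}, k >= 2 -> mean 0.5
  sc <- annotationScore("GENEA", "P1", corpus, db, pr, aliases = "GENEA",
                        k = 10, pathwaySet = "P1")
  expect_equal(sc, 0.5)
  # unmatched gene: missing value, not 0
  expect_true(is.na(annotationScore("GENEB", "P1", corpus, db, pr,
                                    aliases = "GENEB", pathwaySet = "P1")))
})

test_that("the score table matches single calls and ignores row order", {
  cfg <- syntheticConfig(nGenes = 60, nPathways = 3, nAbstracts = 40,
                         nPlantedGenes = 5, seed = 13)
  db <- makeToyPathwayDb(cfg)
  corp <- makeAbstractCorpus(db, cfg)
  pws <- db@topLevel
  genes <- c(corp$plantedGenes[1:3], "ZZNOMATCH")
  tab <- nlpValidationScores(genes, pws, corp$corpus, db, corp$provider)
  expect_identical(dim(tab), c(4L, 3L))
  one <- annotationScore(genes[1], pws[1], corp$corpus, db, corp$provider,
                         aliases = genes[1], pathwaySet = pws)
  expect_equal(tab[genes[1], pws[1]], one, tolerance = 1e-12)
  expect_true(all(is.na(tab["ZZNOMATCH", ])))
  # invariant to gene ordering and corpus shuffling
  tab2 <- nlpValidationScores(rev(genes), pws,
                              corp$corpus[sample(nrow(corp$corpus)), ],
                              db, corp$provider)
  expect_equal(tab2[genes, pws], tab, tolerance = 1e-12)
})

test_that("planted on-topic abstracts score their pathway highest", {
  cfg <- syntheticConfig(nGenes = 60, nPathways = 4, nAbstracts = 60,
                         nPlantedGenes = 6, seed = 29)
  db <- makeToyPathwayDb(cfg)
  corp <- makeAbstractCorpus(db, cfg)
  pr <- corp$provider
  # provider determinism
  v1 <- pr$embed(corp$corpus$text[1])
  expect_identical(pr$embed(corp$corpus$text[1]), v1)
  expect_length(v1, 384)
  # every abstract matches its planted gene
  for (i in seq_len(nrow(corp$corpus))) {
    g <- corp$corpus$gene[i]
    expect_true(corp$corpus$pmid[i] %in%
                  matchAbstracts(corp$corpus, g)$pmid)
  }
  # on-topic abstracts are closer to the target pathway than off-topic ones
  simT <- vapply(corp$corpus$text, function(tx)
    eventSimilarity(corp$targetPathway, pr$embed(tx), db, pr), numeric(1))
  onTopic <- vapply(corp$corpus$text, function(tx)
    any(grepl("pw1term", tx)), logical(1))
  expect_gt(min(simT[onTopic]), max(simT[!onTopic]))
})
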