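test_that("the Hill transfer function matches its closed form", {
  expect_equal(hill(0.5, K = 0.5, n = 4), 0.5)   # half-saturation
  expect_identical(hill(0, K = 0.5, n = 4), 0)
  expect_equal(hill(1, K = 0.5, n = 4), 1 / (1 + 0.0625))
  expect_equal(hill(c(0, 0.5, 1)), c(0, 0.5, 1 / 1.0625))
  expect_error(hill(1.2), "\\[0,1\\]")
  expect_error(hill(0.5, K = 0), "K")
  expect_error(hill(0.5, n = 0.5), "n")
})

test_that("pathway compilation preserves roles with deterministic ordering", {
  db <- chainDb()
  net <- pathwayToNetwork(db, "P2N")             # single reaction X -> A
  expect_identical(net@entityNodes, c("E_A", "E_X"))
  expect_identical(net@reactionNodes, "R1")
  expect_identical(nrow(net@edges), 2L)
  expect_setequal(net@edges$role, c("input", "output"))
  # catalyst edge appears when present
  db2 <- db
  db2@reactions[["R1"]]$catalysts <- "E_G"
  net2 <- pathwayToNetwork(db2, "P2N")
  expect_true(any(net2@edges$role == "catalyst" & net2@edges$source == "E_G"))
  # stable across runs
  expect_identical(pathwayToNetwork(db, "PCH"), pathwayToNetwork(db, "PCH"))
  # pathway without reactions errors
  db3 <- tinyDb()
  expect_error(pathwayToNetwork(db3, "P2"), "no reactions")
})

test_that("a clamped chain converges to the Hill fixed point", {
  net <- pathwayToNetwork(chainDb(), "P2N", hillK = 0.5, hillN = 4)
  tr <- simulateNetwork(net, steps = 100, tol = 1e-9)
  expect_true(tr$converged)
  expect_equal(unname(tr$trace[nrow(tr$trace), "E_A"]), hill(1, 0.5, 4),
               tolerance = 1e-6)
  expect_equal(hill(1, 0.5, 4), 0.9412, tolerance = 1e-4)
  # a large tolerance converges almost immediately
  trLoose <- simulateNetwork(net, tol = 0.999)
  expect_true(trLoose$converged)
  expect_lte(trLoose$steps, 2)
})

test_that("zero-strength perturbations reproduce the baseline exactly", {
  for (seed in 1:25) {
    net <- randomNetwork(seed)
    base <- simulateNetwork(net, steps = 40, tol = 0)
    tgt <- setNames(rep(0, 3), sample(net@entityNodes, 3))
    for (mode in c("activation", "inhibition")) {
      pert <- simulateNetwork(net, steps = 40, tol = 0,
                              pert = perturbation(mode, tgt))
      expect_identical(pert$trace, base$trace)
      for (nd in outputNodes(net)) {
        expect_identical(aucImpact(base, pert, nd), 0)
      }
    }
    expect_true(all(base$trace >= 0 & base$trace <= 1))
  }
})

test_that("activities stay in [0,1] under arbitrary perturbations", {
  for (seed in 26:45) {
    net <- randomNetwork(seed)
    set.seed(seed)
    tgt <- setNames(runif(3), sample(net@entityNodes, 3))
    for (mode in c("activation", "inhibition")) {
      tr <- simulateNetwork(net, steps = 30, tol = 0,
                            pert = perturbation(mode, tgt))
      expect_true(all(tr$trace >= 0 & tr$trace <= 1))
      expect_identical(nrow(tr$trace), 31L)      # series length T + 1
    }
  }
})

test_that("AUC impact handles extremes and mismatches", {
  mk <- function(vals) {
    structure(list(trace = matrix(vals, nrow = 5, ncol = 1,
                                  dimnames = list(NULL, "n1")),
                   steps = 4L, converged = TRUE), class = "SimulationTrace")
  }
  expect_identical(aucImpact(mk(0.3), mk(0.3), "n1"), 0)
  expect_equal(aucImpact(mk(0), mk(1), "n1"), 1)
  expect_equal(aucImpact(mk(1), mk(0), "n1"), -1)
  bad <- mk(0.5); bad$steps <- 3L; bad$trace <- bad$trace[1:4, , drop = FALSE]
  expect_error(aucImpact(mk(0), bad, "n1"), "do not match")
  expect_error(aucImpact(mk(0), mk(0), "nope"), "unknown node")
})

test_that("chain-head injection raises activation and lowers inhibition scores", {
  db <- chainDb()
  fis <- setNames(1.0, pairKey("G", "X"))
  res <- simulationScores("G", fis, db, "PCH", initSource = 0.25)
  expect_gt(res$average_activation, 0)
  expect_lt(res$average_inhibition, 0)
  # the averages are the means of the per-output impacts
  expect_equal(res$average_activation, mean(res$per_output$activation))
  expect_equal(res$average_inhibition, mean(res$per_output$inhibition))
  expect_setequal(res$per_output$node, c("E_A", "E_B"))
  # zero-score FIs leave the pathway untouched
  res0 <- simulationScores("G", setNames(0, pairKey("G", "X")), db, "PCH",
                           initSource = 0.25)
  expect_identical(res0$average_activation, 0)
  expect_identical(res0$average_inhibition, 0)
  # no partner in the pathway: zeros with a warning
  expect_warning(
    resNA <- simulationScores("G", setNames(.9, "G|ZZ"), db, "PCH"),
    "no predicted FI partners")
  expect_identical(resNA$average_activation, 0)
})

test_that("activation impact is monotone in the injected strength", {
  db <- chainDb()
  sweep <- vapply(seq(0, 1, by = 0.2), function(s) {
    simulationScores("G", setNames(s, pairKey("G", "X")), db, "PCH",
                     initSource = 0.25)$average_activation
  }, numeric(1))
  expect_true(all(diff(sweep) >= 0))
  expect_gt(sweep[length(sweep)], sweep[1])
})

test_that("simulation traces are bit-identical across repeated runs", {
  net <- randomNetwork(99)
  tgt <- setNames(c(0.4, 0.7), net@entityNodes[1:2])
  a <- simulateNetwork(net, steps = 50, tol = 0,
                       pert = perturbation("activation", tgt))
  b <- simulateNetwork(net, steps = 50, tol = 0,
                       pert = perturbation("activation", tgt))
  expect_identical(a, b)
})
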