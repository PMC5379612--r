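# Posterior event decoding against exhaustive enumeration, limits, and
# agreement with simulated ground truth.

test_that("event posteriors equal brute-force enumeration on a 3-leaf tree", {
  tr <- threeLeafTree()
  r <- BDGRates(0.6, 0.15, 1.0)
  M <- 5
  counts <- rbind(f1 = c(A = 1, B = 0, C = 2), f2 = c(A = 0, B = 0, C = 1),
                  f3 = c(A = 2, B = 2, C = 0))
  model <- new("FittedBDGModel", tree = tr, rates = r, logLik = 0,
               trace = data.frame(round = 1L, description = "fixed",
                                  logLik = 0),
               M = as.integer(M), conditioned = FALSE, converged = TRUE)
  post <- eventTable(posteriorEvents(model, counts, truncTol = 1))
  for (f in rownames(counts)) {
    oracle <- bruteForcePosteriors(tr, counts[f, ], r, M)
    got <- post[post$family == f, ]
    got <- got[match(oracle$edge, got$edge), ]
    expect_equal(got$p_gain, unname(oracle$posterior[, "gain"]),
                 tolerance = 1e-6)
    expect_equal(got$p_loss, unname(oracle$posterior[, "loss"]),
                 tolerance = 1e-6)
    expect_equal(got$p_expansion, unname(oracle$posterior[, "expansion"]),
                 tolerance = 1e-6)
    expect_equal(got$p_reduction, unname(oracle$posterior[, "reduction"]),
                 tolerance = 1e-6)
  }
})

test_that("posteriors are probabilities and exclusive events do not overlap", {
  tr <- threeLeafTree()
  r <- BDGRates(0.6, 0.15, 1.0, categoryShape = 0.8, nCategories = 2L)
  counts <- rbind(f1 = c(A = 1, B = 0, C = 2), f2 = c(A = 0, B = 3, C = 1))
  model <- new("FittedBDGModel", tree = tr, rates = r, logLik = 0,
               trace = data.frame(round = 1L, description = "fixed",
                                  logLik = 0),
               M = 15L, conditioned = FALSE, converged = TRUE)
  p <- eventTable(posteriorEvents(model, counts))
  expect_true(all(p$p_gain >= 0 & p$p_gain <= 1))
  expect_true(all(p$p_gain + p$p_loss <= 1 + 1e-12))
  expect_true(all(p$p_gain + p$p_expansion <= 1 + 1e-12))
  expect_true(all(p$p_loss + p$p_reduction <= 1 + 1e-12))
})

test_that("a certain loss is decoded as such in the vanishing-gain limit", {
  # profile (A = 2, B = 0) with a near-zero branch to A: the root state is
  # pinned at 2 (gains on the tiny A branch are O((kappa*t)^2), vastly less
  # likely than the O(kappa^2) prior), so the edge to B must carry a loss
  tr <- twoLeafTree(1e-3, 0.2)
  r <- BDGRates(1e-6, 0, 1.0)
  counts <- rbind(f1 = c(A = 2, B = 0))
  model <- new("FittedBDGModel", tree = tr, rates = r, logLik = 0,
               trace = data.frame(round = 1L, description = "fixed",
                                  logLik = 0),
               M = 10L, conditioned = FALSE, converged = TRUE)
  p <- eventTable(posteriorEvents(model, counts, truncTol = 1))
  ti <- DefenseFlux:::treeIndex(tr)
  bTip <- which(ti$tree$tip.label == "B")
  lossB <- p$p_loss[p$edge == paste0(ti$root, "->", bTip)]
  expect_equal(lossB, 1, tolerance = 1e-3)
  expect_lt(sum(p$p_gain), 1e-3)
})

test_that("profiles impossible under the model raise a clear error", {
  # kappa = 0 with the stationary prior makes any non-zero profile impossible
  tr <- twoLeafTree(0.2, 0.2)
  model <- new("FittedBDGModel", tree = tr, rates = BDGRates(0, 0, 1),
               logLik = 0,
               trace = data.frame(round = 1L, description = "fixed",
                                  logLik = 0),
               M = 10L, conditioned = FALSE, converged = TRUE)
  counts <- rbind(f1 = c(A = 2, B = 0))
  expect_error(posteriorEvents(model, counts, truncTol = 1),
               "zero likelihood")
})

test_that("summarizeEvents totals are additive over family subsets", {
  tr <- threeLeafTree()
  r <- BDGRates(0.6, 0.15, 1.0)
  counts <- rbind(f1 = c(A = 1, B = 0, C = 2), f2 = c(A = 0, B = 3, C = 1),
                  f3 = c(A = 1, B = 1, C = 1))
  model <- new("FittedBDGModel", tree = tr, rates = r, logLik = 0,
               trace = data.frame(round = 1L, description = "fixed",
                                  logLik = 0),
               M = 15L, conditioned = FALSE, converged = TRUE)
  tAll <- eventTotals(summarizeEvents(posteriorEvents(model, counts)))
  t12 <- eventTotals(summarizeEvents(posteriorEvents(model, counts,
                                                     families = c("f1", "f2"))))
  t3 <- eventTotals(summarizeEvents(posteriorEvents(model, counts,
                                                    families = "f3")))
  expect_equal(tAll, t12 + t3, tolerance = 1e-10)
})

test_that("posterior totals track logged simulation truth", {
  # light version of the acceptance check: decode with the TRUE rates and
  # compare expected event totals against the generator's event log
  tr <- simulateTree(6, seed = 5, depth = 0.3)
  cfg <- SimConfig(seed = 5, nLeaves = 6, nFamilies = 600,
                   defenseFraction = 0, kappa = 0.5, lambda = 0.1, mu = 1.0)
  sim <- simulateFamilies(tr, cfg)
  r <- BDGRates(0.5, 0.1, 1.0)
  model <- new("FittedBDGModel", tree = tr, rates = r, logLik = 0,
               trace = data.frame(round = 1L, description = "true rates",
                                  logLik = 0),
               M = max(3L * max(sim$counts), 20L), conditioned = FALSE,
               converged = TRUE)
  tot <- eventTotals(summarizeEvents(posteriorEvents(model, sim$counts)))
  truth <- colSums(sim$truth[, c("gain", "loss", "expansion", "reduction")])
  # gains and losses are frequent enough for a tight relative check
  expect_lt(abs(tot["gains"] - truth["gain"]) / truth["gain"], 0.15)
  expect_lt(abs(tot["losses"] - truth["loss"]) / truth["loss"], 0.15)
})
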