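# Synthetic ATGC generator: determinism, distributional agreement with the
# analytic chain, and chromosome-map structure.

test_that("simulation is deterministic in the seed", {
  cfg <- SimConfig(seed = 17, nLeaves = 5, nFamilies = 120)
  a <- simulateATGC(cfg)
  b <- simulateATGC(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$maps$g1@family, b$maps$g1@family)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c2 <- simulateATGC(SimConfig(seed = 18, nLeaves = 5, nFamilies = 120))
  expect_false(identical(a$counts, c2$counts))
})

test_that("root draws follow the stationary distribution", {
  tr <- simulateTree(2, seed = 1, depth = 1e-9)  # effectively frozen tree
  cfg <- SimConfig(seed = 12, nLeaves = 2, nFamilies = 20000,
                   defenseFraction = 0, kappa = 0.5, lambda = 0.1, mu = 1.0)
  sim <- simulateFamilies(tr, cfg)
  x <- sim$counts[, 1]
  # stationary NB(size = kappa/lambda, prob = 1 - lambda/mu)
  expect_equal(mean(x), 0.5 / 0.9, tolerance = 0.05)
  expect_equal(mean(x == 0), dnbinom(0, size = 5, prob = 0.9),
               tolerance = 0.02)
})

test_that("leaf-count distribution matches the analytic transition law", {
  # one parent-child edge of length t: empirical end states from the
  # generator versus the uniformized transition matrix
  tr <- twoLeafTree(0.5, 1e-9)  # tip B pins the root state draw
  cfg <- SimConfig(seed = 3, nLeaves = 2, nFamilies = 30000,
                   defenseFraction = 0, kappa = 0.5, lambda = 0.1, mu = 1.0)
  sim <- simulateFamilies(tr, cfg)
  from1 <- sim$counts[sim$counts[, "B"] == 1, "A"]  # root state was 1
  P <- transitionMatrix(c(0.5, 0.1, 1.0), 0.5, 30)
  for (m in 0:3) {
    p <- P[2, m + 1]
    se <- sqrt(p * (1 - p) / length(from1))
    expect_lt(abs(mean(from1 == m) - p), 4 * se)
  }
})

test_that("truth log is consistent with the leaf counts", {
  tr <- simulateTree(5, seed = 4, depth = 0.3)
  cfg <- SimConfig(seed = 4, nLeaves = 5, nFamilies = 200)
  sim <- simulateFamilies(tr, cfg)
  ti <- DefenseFlux:::treeIndex(tr)
  # terminal-edge child states in the log equal the observed counts
  for (tip in seq_along(ti$tree$tip.label)) {
    e <- which(ti$edge[, 2] == tip)
    lab <- paste0(ti$edge[e, 1], "->", tip)
    logged <- sim$truth$child_state[sim$truth$edge == lab]
    expect_identical(logged,
                     unname(sim$counts[sim$truth$family[sim$truth$edge == lab],
                                       ti$tree$tip.label[tip]]))
  }
  # event indicators recompute from the states
  with(sim$truth, {
    expect_identical(gain, as.integer(parent_state == 0 & child_state >= 1))
    expect_identical(loss, as.integer(parent_state >= 1 & child_state == 0))
  })
})

test_that("chromosome maps place exactly the present gene copies", {
  cfg <- SimConfig(seed = 6, nLeaves = 4, nFamilies = 150,
                   defenseFraction = 0.2)
  atgc <- simulateATGC(cfg)
  for (g in colnames(atgc$counts)) {
    m <- atgc$maps[[g]]
    placed <- table(m@family)
    present <- atgc$counts[atgc$counts[, g] > 0, g]
    expect_identical(sort(names(placed)), sort(names(present)))
    expect_identical(as.integer(placed[names(present)]), unname(present))
    expect_identical(m@geneClass,
                     unname(atgc$annotations[m@family]))
  }
})

test_that("island concentration produces detectable clustering, zero does not", {
  mkP <- function(conc, seed) {
    cfg <- SimConfig(seed = seed, nLeaves = 2, nFamilies = 500,
                     defenseFraction = 0.06, islandConcentration = conc,
                     kappa = 1.5, lambda = 0.1, mu = 1.0)
    atgc <- simulateATGC(cfg)
    vapply(atgc$maps, function(m)
      tryCatch(pValue(colocalizationTest(m, nReps = 400, seed = seed)),
               error = function(e) NA_real_), numeric(1))
  }
  pIsl <- unlist(lapply(1:3, function(s) mkP(0.95, s)))
  pUni <- unlist(lapply(1:3, function(s) mkP(0, s)))
  expect_lt(median(pIsl, na.rm = TRUE), 0.05)
  expect_gt(median(pUni, na.rm = TRUE), 0.1)
})

test_that("strand persistence controls directon length", {
  cfg1 <- SimConfig(seed = 9, nLeaves = 2, nFamilies = 400,
                    strandPersistence = 0.95)
  cfg2 <- SimConfig(seed = 9, nLeaves = 2, nFamilies = 400,
                    strandPersistence = 0.5)
  m1 <- simulateATGC(cfg1)$maps$g1
  m2 <- simulateATGC(cfg2)$maps$g1
  len <- function(m) mean(lengths(directons(buildDirectons(m))))
  expect_gt(len(m1), 2 * len(m2))
})

test_that("simulation config round-trips through its text serialization", {
  cfg <- SimConfig(seed = 5, nLeaves = 7, nFamilies = 250,
                   defenseFraction = 0.1, kappa = 0.7, lambda = 0.05,
                   mu = 0.9, defenseMultiplier = c(1, 1, 1.5),
                   islandConcentration = 0.4, strandPersistence = 0.75)
  f <- tempfile()
  writeSimConfig(cfg, f)
  back <- readSimConfig(f)
  for (sl in slotNames(cfg))
    expect_equal(slot(back, sl), slot(cfg, sl), tolerance = 1e-10,
                 label = sl)
})
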