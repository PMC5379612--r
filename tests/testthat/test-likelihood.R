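# Pruning likelihood versus brute-force summation, conditioning, and the
# time-rescaling identity.

test_that("pruning equals brute-force summation on a 2-leaf tree", {
  tr <- twoLeafTree()
  r <- BDGRates(0.5, 0.1, 1.0)
  M <- 12
  for (prof in list(c(A = 0, B = 1), c(A = 2, B = 0), c(A = 3, B = 3))) {
    expect_equal(familyLogLikelihood(tr, prof, r, M, truncTol = 1),
                 log(bruteForceLik(tr, prof, r, M)), tolerance = 1e-9)
  }
})

test_that("pruning equals brute-force summation on a 3-leaf tree", {
  tr <- threeLeafTree()
  r <- BDGRates(0.8, 0.2, 1.2)
  M <- 6
  for (prof in list(c(A = 1, B = 0, C = 2), c(A = 0, B = 0, C = 1))) {
    expect_equal(familyLogLikelihood(tr, prof, r, M, truncTol = 1),
                 log(bruteForceLik(tr, prof, r, M)), tolerance = 1e-9)
  }
})

test_that("conditioned profile probabilities sum to 1 over observable profiles", {
  tr <- twoLeafTree(0.3, 0.3)
  r <- BDGRates(0.3, 0.05, 1.0)
  M <- 14
  tot <- 0
  for (a in 0:9) for (b in 0:9) {
    if (a == 0 && b == 0) next
    tot <- tot + exp(familyLogLikelihood(tr, c(A = a, B = b), r, M,
                                         conditionOnObserved = TRUE,
                                         truncTol = 1))
  }
  expect_equal(tot, 1, tolerance = 1e-4)  # remainder is profiles with counts > 9
})

test_that("likelihood is invariant to leaf label permutation", {
  tr <- threeLeafTree()
  r <- BDGRates(0.5, 0.1, 1.0)
  prof <- c(A = 2, B = 0, C = 1)
  ll1 <- familyLogLikelihood(tr, prof, r, 15)
  ll2 <- familyLogLikelihood(tr, prof[c("C", "A", "B")], r, 15)
  expect_identical(ll1, ll2)
})

test_that("joint rate scaling equals branch-length rescaling", {
  tr <- threeLeafTree()
  prof <- c(A = 1, B = 2, C = 0)
  c0 <- 1.7
  r1 <- BDGRates(0.5 * c0, 0.1 * c0, 1.0 * c0)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * c0
  r2 <- BDGRates(0.5, 0.1, 1.0)
  expect_equal(familyLogLikelihood(tr, prof, r1, 20),
               familyLogLikelihood(tr2, prof, r2, 20), tolerance = 1e-12)
})

test_that("edge multipliers scale the corresponding branch lengths", {
  tr <- threeLeafTree()
  prof <- c(A = 1, B = 2, C = 0)
  em <- c(2, 0.5, 1, 1.3)
  r <- BDGRates(0.5, 0.1, 1.0, edgeMultipliers = em)
  tr2 <- ape::reorder.phylo(tr, "postorder")
  tr2$edge.length <- tr2$edge.length * em
  expect_equal(familyLogLikelihood(tr, prof, r, 20),
               familyLogLikelihood(tr2, prof, BDGRates(0.5, 0.1, 1.0), 20),
               tolerance = 1e-12)
})

test_that("category mixture averages single-category likelihoods", {
  tr <- twoLeafTree()
  prof <- c(A = 1, B = 0)
  M <- 20
  shape <- 0.7
  rK <- BDGRates(0.5, 0.1, 1.0, categoryShape = shape, nCategories = 3L)
  mult <- DefenseFlux:::gammaCategoryMultipliers(shape, 3)
  perCat <- vapply(mult, function(m)
    exp(familyLogLikelihood(tr, prof, BDGRates(0.5 * m, 0.1 * m, 1.0 * m), M)),
    numeric(1))
  expect_equal(familyLogLikelihood(tr, prof, rK, M), log(mean(perCat)),
               tolerance = 1e-10)
})

test_that("gamma category multipliers are slice means with mean 1", {
  for (shape in c(0.3, 1, 5)) {
    for (K in 2:4) {
      m <- DefenseFlux:::gammaCategoryMultipliers(shape, K)
      expect_equal(mean(m), 1, tolerance = 1e-12)
      expect_true(all(diff(m) > 0))
      # Monte Carlo slice means as oracle
      set.seed(1)
      x <- sort(rgamma(4.8e5, shape, rate = shape))  # divisible by K = 2..4
      mc <- colMeans(matrix(x, ncol = K))
      expect_equal(m, mc / mean(mc), tolerance = 0.02)
    }
  }
})

test_that("M smaller than the largest observed count is rejected", {
  tr <- twoLeafTree()
  expect_error(familyLogLikelihood(tr, c(A = 9, B = 0), BDGRates(1, 0, 1), 5),
               "M smaller")
})
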