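# Transition probabilities of the birth-death-gain chain.
# [DERIVED] matrix-exponential and closed-form oracles; [TRIVIAL] structure.

test_that("transitionMatrix matches the matrix exponential of the generator", {
  skip_if_not_installed("Matrix")
  for (r in list(c(0.5, 0.1, 1.0), c(2, 0, 0.7), c(0.05, 0.4, 0.5))) {
    for (t in c(0.05, 0.3, 2)) {
      M <- 40
      P <- transitionMatrix(r, t, M)
      Q <- DefenseFlux:::bdgGenerator(r[1], r[2], r[3], M)
      E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
      expect_lt(max(abs(P - E)), 1e-10)
    }
  }
})

test_that("pure-death chain matches the binomial closed form", {
  # kappa = lambda = 0: copies die independently at rate mu, so
  # P(n -> m) = C(n, m) s^m (1-s)^(n-m) with s = exp(-mu t)
  mu <- 1.3; t <- 0.6; M <- 12
  P <- transitionMatrix(c(0, 0, mu), t, M)
  s <- exp(-mu * t)
  for (n in 0:M) {
    expect_equal(unname(P[n + 1, 1:(n + 1)]), dbinom(0:n, n, s),
                 tolerance = 1e-12)
  }
})

test_that("pure-immigration chain matches the Poisson closed form", {
  # lambda = mu = 0: arrivals are Poisson(kappa t), no deaths
  kappa <- 0.8; t <- 0.5; M <- 30
  P <- transitionMatrix(c(kappa, 0, 0), t, M)
  expect_equal(unname(P[1, 1:20]), dpois(0:19, kappa * t), tolerance = 1e-12)
})

test_that("Chapman-Kolmogorov holds away from the truncation boundary", {
  r <- c(0.5, 0.1, 1.0); M <- 50
  P1 <- transitionMatrix(r, 0.2, M)
  P2 <- transitionMatrix(r, 0.3, M)
  P3 <- transitionMatrix(r, 0.5, M)
  # rows well inside the truncation window compose exactly
  expect_lt(max(abs((P1 %*% P2 - P3)[1:10, 1:10])), 1e-9)
})

test_that("t = 0 returns the identity and rows never exceed 1", {
  P0 <- transitionMatrix(c(1, 0.2, 1), 0, 10)
  expect_equal(unname(P0), diag(11))
  P <- transitionMatrix(c(1, 0.2, 1), 1.5, 10)
  expect_true(all(P >= 0))
  expect_true(all(rowSums(P) <= 1 + 1e-12))
})

test_that("truncation check raises dfxTruncationError naming a larger M", {
  expect_error(transitionMatrix(c(5, 0.5, 1), t = 2, M = 3, checkStates = 3),
               class = "dfxTruncationError")
  err <- tryCatch(transitionMatrix(c(5, 0.5, 1), 2, 3, checkStates = 3),
                  dfxTruncationError = function(e) e)
  expect_match(conditionMessage(err), "increase M")
})

test_that("stationary prior is invariant under the transition matrix", {
  r <- c(0.5, 0.1, 1.0); M <- 60
  pr <- rootPrior(r, M)
  P <- transitionMatrix(r, 0.7, M)
  expect_lt(max(abs((pr %*% P) - pr)[1:40]), 1e-10)
})

test_that("rootPrior matches the NB / Poisson closed forms and rejects lambda >= mu", {
  M <- 80
  prNB <- rootPrior(c(0.5, 0.1, 1.0), M)
  expect_equal(unname(prNB[1:20]),
               dnbinom(0:19, size = 5, prob = 0.9) /
                 sum(dnbinom(0:M, size = 5, prob = 0.9)), tolerance = 1e-12)
  prP <- rootPrior(c(2, 0, 1), M)
  expect_equal(prP[1], dpois(0, 2) / sum(dpois(0:M, 2)), tolerance = 1e-12)
  expect_error(rootPrior(c(1, 1.2, 1), 20), "stationary")
})

test_that("Gillespie end-state frequencies agree with the transition row", {
  # [DERIVED] independent stochastic oracle for the same chain (light version;
  # the 1e6-replicate comparison runs in the acceptance tests)
  r <- c(0.5, 0.2, 1.0); t <- 0.4; M <- 30; n0 <- 2L
  P <- transitionMatrix(r, t, M)
  set.seed(11)
  end <- DefenseFlux:::simulateBdiEdge(rep(n0, 50000L), t, r[1], r[2], r[3])
  for (m in 0:5) {
    phat <- mean(end == m)
    p <- P[n0 + 1, m + 1]
    se <- sqrt(p * (1 - p) / 50000)
    expect_lt(abs(phat - p), 4 * se + 1e-12)
  }
})
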