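# Directons, nearest-neighbour medians and the randomization tests.

mkMap <- function(strand, cls = NULL, circular = TRUE) {
  n <- length(strand)
  if (is.null(cls)) cls <- rep("non-defense", n)
  ChromosomeMap("chr", strand, sprintf("f%03d", seq_len(n)), cls,
                circular = circular)
}

test_that("directons are maximal co-directed runs with circular wrap merging", {
  # circular: + + - - + -> the trailing + wraps onto the leading + +, so the
  # runs are {4, 0, 1} and {2, 3}
  d <- directons(buildDirectons(mkMap(c("+", "+", "-", "-", "+"))))
  expect_length(d, 2)
  sets <- lapply(d, sort)
  expect_true(any(vapply(sets, identical, NA, c(0L, 1L, 4L))))
  expect_true(any(vapply(sets, identical, NA, c(2L, 3L))))
  # linear: the same strands do not merge over the ends
  dl <- directons(buildDirectons(mkMap(c("+", "+", "-", "-", "+"),
                                       circular = FALSE)))
  expect_length(dl, 3)
  expect_identical(lapply(dl, sort), list(c(0L, 1L), c(2L, 3L), 4L))
  # uniform strand collapses to a single directon
  du <- directons(buildDirectons(mkMap(rep("+", 6))))
  expect_length(du, 1)
  expect_identical(sort(du[[1]]), 0:5)
})

test_that("directon members always partition the gene set", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    circ <- i %% 2 == 0
    ds <- buildDirectons(mkMap(sample(c("+", "-"), n, replace = TRUE),
                               circular = circ))
    all <- sort(unlist(directons(ds)))
    expect_identical(all, 0:(n - 1L))
  }
})

test_that("defense flag propagates from any member gene", {
  cls <- c("non-defense", "RM", "non-defense", "non-defense")
  ds <- buildDirectons(mkMap(c("+", "+", "-", "-"), cls))
  flagged <- vapply(directons(ds), function(m) 1L %in% m, NA)
  expect_identical(ds@defense, flagged)
})

test_that("nearest-neighbour median matches the quadratic oracle", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    k <- sample(2:min(9, n), 1)
    pos <- sample(0:(n - 1), k)
    circ <- i %% 2 == 0
    expect_equal(nearestNeighborMedian(pos, n, circ),
                 bruteForceNNMedian(pos, n, circ))
  }
})

test_that("the circular statistic is rotation invariant", {
  pos <- c(3, 9, 40, 41, 77)
  n <- 100
  base <- nearestNeighborMedian(pos, n, circular = TRUE)
  for (shift in c(1, 23, 59))
    expect_equal(nearestNeighborMedian((pos + shift) %% n, n, TRUE), base)
})

test_that("clustered defense genes give a small p, uniform ones do not", {
  set.seed(8)
  n <- 300
  cls <- rep("non-defense", n)
  cls[51:62] <- "RM"  # one tight island of 12 genes
  strand <- sample(c("+", "-"), n, replace = TRUE)
  m <- ChromosomeMap("chr", strand, sprintf("f%03d", 1:n), cls)
  res <- colocalizationTest(m, level = "gene", nReps = 2000, seed = 5)
  expect_lte(pValue(res), 0.001)
  # the same genes scattered deterministically far apart are not clustered
  cls2 <- rep("non-defense", n)
  cls2[seq(1, n, by = 25)] <- "RM"
  m2 <- ChromosomeMap("chr", strand, sprintf("f%03d", 1:n), cls2)
  expect_gt(pValue(colocalizationTest(m2, level = "gene", nReps = 2000,
                                      seed = 5)), 0.5)
})

test_that("degenerate tests (all units are defense) return p = 1", {
  m <- mkMap(c("+", "-", "+"), rep("TA", 3))
  res <- colocalizationTest(m, level = "gene", nReps = 100, seed = 1)
  expect_true(res@degenerate)
  expect_equal(pValue(res), 1)
})

test_that("p-values are reproducible under the recorded seed", {
  set.seed(99)
  n <- 120
  cls <- rep("non-defense", n); cls[sample(n, 8)] <- "Abi"
  m <- mkMap(sample(c("+", "-"), n, replace = TRUE), cls)
  r1 <- colocalizationTest(m, nReps = 500, seed = 42)
  r2 <- colocalizationTest(m, nReps = 500, seed = 42)
  expect_identical(pValue(r1), pValue(r2))
})

test_that("event-level test resamples from defense positions only", {
  n <- 200
  cls <- rep("non-defense", n)
  # 10 contiguous defense genes with events, plus 20 scattered without
  defPos <- c(0:9, seq(20, 115, by = 5))
  cls[defPos + 1] <- "RM"
  m <- mkMap(rep("+", n), cls)
  res <- eventColocalizationTest(0:9, defPos, m, level = "gene",
                                 nReps = 1000, seed = 3)
  expect_lt(pValue(res), 0.05)
  expect_error(eventColocalizationTest(c(0, 150), defPos, m), "subset")
})
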