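# Shared oracles for the numerical tests. These are deliberately slow,
# transparent implementations that share no code with the package internals.

# Brute-force likelihood of a leaf-count profile on a rooted tree by explicit
# summation over all internal-node states in 0..M. `tipCounts` is a named
# vector; `P(t)` matrices come from the supplied transition function.
bruteForceLik <- function(tree, profile, rates, M, Pfun = transitionMatrix) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) Pfun(rates, tree$edge.length[e], M))
  prior <- rootPrior(rates, M)
  grid <- do.call(expand.grid, rep(list(0:M), length(internal)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    state <- integer(nnode)
    state[seq_len(ntip)] <- as.integer(profile[tree$tip.label])
    state[internal] <- as.integer(grid[g, ])
    p <- prior[state[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- state[tree$edge[e, 1]]
      b <- state[tree$edge[e, 2]]
      p <- p * Ps[[e]][a + 1L, b + 1L]
    }
    total <- total + p
  }
  total
}

# Brute-force per-edge event posteriors on a rooted tree: enumerate all
# internal states, accumulate joint mass by (parent, child) event indicator.
bruteForcePosteriors <- function(tree, profile, rates, M) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  nE <- nrow(tree$edge)
  Ps <- lapply(seq_len(nE),
               function(e) transitionMatrix(rates, tree$edge.length[e], M))
  prior <- rootPrior(rates, M)
  grid <- do.call(expand.grid, rep(list(0:M), length(internal)))
  ev <- matrix(0, nE, 4, dimnames = list(NULL, c("gain", "loss",
                                                 "expansion", "reduction")))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    state <- integer(nnode)
    state[seq_len(ntip)] <- as.integer(profile[tree$tip.label])
    state[internal] <- as.integer(grid[g, ])
    p <- prior[state[root] + 1L]
    for (e in seq_len(nE)) {
      a <- state[tree$edge[e, 1]]
      b <- state[tree$edge[e, 2]]
      p <- p * Ps[[e]][a + 1L, b + 1L]
    }
    total <- total + p
    for (e in seq_len(nE)) {
      a <- state[tree$edge[e, 1]]
      b <- state[tree$edge[e, 2]]
      ev[e, 1] <- ev[e, 1] + p * (a == 0 && b >= 1)
      ev[e, 2] <- ev[e, 2] + p * (a >= 1 && b == 0)
      ev[e, 3] <- ev[e, 3] + p * (b > a && a >= 1)
      ev[e, 4] <- ev[e, 4] + p * (a > b && b >= 1)
    }
  }
  list(posterior = ev / total, lik = total,
       edge = paste0(tree$edge[, 1], "->", tree$edge[, 2]))
}

# O(k^2) nearest-neighbour median, independent of the package's sorted-gap
# implementation.
bruteForceNNMedian <- function(positions, n, circular) {
  k <- length(positions)
  d <- sapply(seq_len(k), function(i) {
    other <- positions[-i]
    raw <- abs(other - positions[i])
    if (circular) raw <- pmin(raw, n - raw)
    min(raw)
  })
  median(d)
}

# small fixed trees used across files
twoLeafTree <- function(t1 = 0.4, t2 = 0.7) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2))
}
threeLeafTree <- function() {
  ape::read.tree(text = "((A:0.3,B:0.5):0.2,C:0.6);")
}
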