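# Pruning likelihood over family-size states, shared by fitting and
# posterior decoding. All heavy objects are (M+1) x F matrices so the passes
# reduce to dense matrix products over every family at once.

# Equal-probability discrete gamma multipliers (mean of each quantile slice),
# normalized to mean exactly 1.
gammaCategoryMultipliers <- function(shape, K) {
  if (K == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = shape, rate = shape)
  # mean of X | q_i < X < q_{i+1} for Gamma(shape, shape):
  # shape/rate * [F_{shape+1}(b) - F_{shape+1}(a)] / [F_shape(b) - F_shape(a)]
  upper <- pgamma(q, shape = shape + 1, rate = shape)
  lower <- pgamma(q, shape = shape, rate = shape)
  m <- diff(upper) / diff(lower)
  m / mean(m)
}

# Expand a BDGRates object into per-category effective (kappa, lambda, mu)
# and weights. Joint multipliers are the default; `applies` selects which
# rates a category multiplier scales.
rateCategories <- function(rates, applies = c("kappa", "lambda", "mu")) {
  K <- rates@nCategories
  mult <- gammaCategoryMultipliers(rates@categoryShape, K)
  lapply(seq_len(K), function(k) {
    r <- c(kappa = rates@kappa, lambda = rates@lambda, mu = rates@mu)
    r[applies] <- r[applies] * mult[k]
    list(rates = unname(r), weight = 1 / K)
  })
}

# Tree bookkeeping: postorder edge ordering, children lists, root.
treeIndex <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  list(tree = tree, ntip = ntip, root = root,
       nnode = ntip + tree$Nnode,
       edge = tree$edge, elen = tree$edge.length)
}

# Effective branch lengths: multiplying (kappa, lambda, mu) jointly by a
# factor is a time rescaling, so per-edge multipliers scale edge lengths.
effectiveEdgeLengths <- function(rates, elen) {
  if (length(rates@edgeMultipliers)) {
    if (length(rates@edgeMultipliers) != length(elen))
      stop("edgeMultipliers must have one entry per tree edge")
    elen * rates@edgeMultipliers
  } else elen
}

# Inside (pruning) pass for one rate category.
# counts: F x ntip integer matrix, columns ordered as tree$tip.label.
# Returns per-node partial likelihood matrices (scaled), per-node log scale
# vectors, the per-family log-likelihood, and the cached edge transition
# matrices and per-edge "message" S_e = P_e %*% L[child].
insidePass <- function(ti, counts, catRates, M, elen, checkStates, truncTol) {
  F <- nrow(counts)
  nodes <- ti$nnode
  states <- M + 1L
  Ps <- vector("list", nrow(ti$edge))
  S <- vector("list", nrow(ti$edge))
  L <- vector("list", nodes)
  logScale <- matrix(0, nodes, F)
  for (tip in seq_len(ti$ntip)) {
    Lt <- matrix(0, states, F)
    Lt[cbind(counts[, tip] + 1L, seq_len(F))] <- 1
    L[[tip]] <- Lt
  }
  edgeOfChild <- integer(nodes)
  edgeOfChild[ti$edge[, 2]] <- seq_len(nrow(ti$edge))
  # postorder edges: children appear before their parent edge
  for (e in seq_len(nrow(ti$edge))) {
    child <- ti$edge[e, 2]
    Ps[[e]] <- transitionMatrix(catRates, elen[e], M,
                                checkStates = checkStates, truncTol = truncTol)
    if (is.null(L[[child]])) stop("postorder violated")  # internal invariant
    S[[e]] <- Ps[[e]] %*% L[[child]]
    parent <- ti$edge[e, 1]
    if (is.null(L[[parent]])) {
      L[[parent]] <- S[[e]]
      logScale[parent, ] <- logScale[child, ]
    } else {
      L[[parent]] <- L[[parent]] * S[[e]]
      logScale[parent, ] <- logScale[parent, ] + logScale[child, ]
    }
    # rescale the parent once all of an edge's contribution is in; cheap to
    # do per edge and keeps entries in range
    cm <- apply(L[[parent]], 2, max)
    cm[cm == 0] <- 1
    L[[parent]] <- sweep(L[[parent]], 2, cm, "/")
    logScale[parent, ] <- logScale[parent, ] + log(cm)
  }
  prior <- rootPrior(catRates, M)
  rootLik <- colSums(prior * L[[ti$root]])
  list(L = L, logScale = logScale, Ps = Ps, S = S, prior = prior,
       logLik = log(rootLik) + logScale[ti$root, ])
}

# Log-likelihood per family under the full category mixture; optionally the
# probability of the all-zero profile (for conditioning on observed
# families).
bdgLogLik <- function(tree, counts, rates, M, conditionOnObserved = TRUE,
                      applies = c("kappa", "lambda", "mu"), truncTol = 1e-9,
                      keepPasses = FALSE) {
  ti <- treeIndex(tree)
  counts <- counts[, ti$tree$tip.label, drop = FALSE]
  maxObs <- max(counts)
  if (maxObs > M) stop("M smaller than the maximum observed count")
  elen <- effectiveEdgeLengths(rates, ti$elen)
  cats <- rateCategories(rates, applies)
  K <- length(cats)
  ll <- matrix(NA_real_, nrow(counts), K)
  p0 <- numeric(K)
  passes <- vector("list", K)
  zero <- matrix(0L, 1, ncol(counts),
                 dimnames = list("zero", colnames(counts)))
  for (k in seq_len(K)) {
    ip <- insidePass(ti, counts, cats[[k]]$rates, M, elen,
                     checkStates = 0:maxObs, truncTol = truncTol)
    ll[, k] <- ip$logLik
    if (conditionOnObserved) {
      z <- insidePass(ti, zero, cats[[k]]$rates, M, elen,
                      checkStates = 0L, truncTol = truncTol)
      p0[k] <- exp(z$logLik)
    }
    if (keepPasses) passes[[k]] <- ip
  }
  w <- vapply(cats, `[[`, numeric(1), "weight")
  # log-sum-exp of the category mixture
  mx <- apply(ll, 1, max)
  mix <- mx + log(rowSums(sweep(exp(sweep(ll, 1, mx, "-")), 2, w, "*")))
  p0mix <- sum(w * p0)
  if (conditionOnObserved) mix <- mix - log1p(-p0mix)
  list(perFamily = as.numeric(mix), total = sum(mix), perCategory = ll,
       weights = w, p0 = p0mix, passes = passes, ti = ti, counts = counts,
       elen = elen, cats = cats)
}

#' Log-likelihood of one phyletic profile
#'
#' Probability of the leaf counts of a single gene family under the
#' birth-death-gain model, computed by pruning over family-size states with a
#' stationary root prior, as a mixture over the discrete rate categories.
#' With `conditionOnObserved`, divided by one minus the probability of the
#' all-zero profile (families absent from every genome are unobservable in
#' orthology tables).
#'
#' @param tree rooted `ape::phylo`
#' @param profile named non-negative integer vector of counts, names matching
#'   the tree's tip labels
#' @param rates a [BDGRates-class]
#' @param M truncation bound; must be at least the maximum observed count
#' @param conditionOnObserved logical, default `FALSE`
#' @param truncTol truncation-mass tolerance; exceeding it raises an error
#'   asking for a larger M
#' @return the log-likelihood (a single number)
#' @examples
#' tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
#' familyLogLikelihood(tr, c(A = 1, B = 0), BDGRates(0.5, 0.1, 1), M = 20)
#' @export
familyLogLikelihood <- function(tree, profile, rates, M,
                                conditionOnObserved = FALSE,
                                truncTol = 1e-9) {
  validateSpeciesTree(tree)
  if (!setequal(names(profile), tree$tip.label))
    stop("profile names must match the tree's tip labels")
  counts <- matrix(as.integer(profile[tree$tip.label]), nrow = 1,
                   dimnames = list("fam", tree$tip.label))
  bdgLogLik(tree, counts, rates, M, conditionOnObserved = conditionOnObserved,
            truncTol = truncTol)$perFamily
}
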