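# Posterior decoding of gain / loss / expansion / reduction events on every
# edge, by inside-outside passes over family-size states. Event definitions
# on a parent -> child state pair (a, b):
#   gain       a = 0, b >= 1   (absence -> presence)
#   loss       a >= 1, b = 0   (presence -> absence)
#   expansion  b > a >= 1      (copy-number increase of a present family)
#   reduction  a > b >= 1      (copy-number decrease, family retained)

eventMasks <- function(M) {
  a <- matrix(0:M, M + 1, M + 1)
  b <- t(a)
  list(gain = (a == 0) & (b >= 1),
       loss = (a >= 1) & (b == 0),
       expansion = (b > a) & (a >= 1),
       reduction = (a > b) & (b >= 1))
}

# Outside pass for one category given its inside pass; returns, per edge, the
# four event posteriors as F-vectors (already normalized by the total joint
# mass, so inside/outside scale factors cancel).
decodeCategory <- function(ip, ti, M, F) {
  masks <- eventMasks(M)
  nodes <- ti$nnode
  nEdges <- nrow(ti$edge)
  O <- vector("list", nodes)
  O[[ti$root]] <- matrix(ip$prior, M + 1, F)
  out <- array(NA_real_, dim = c(nEdges, 4, F))
  childrenEdges <- split(seq_len(nEdges), ti$edge[, 1])
  # preorder: reverse postorder visits each parent before its children
  for (e in rev(seq_len(nEdges))) {
    parent <- ti$edge[e, 1]
    child <- ti$edge[e, 2]
    sibs <- setdiff(childrenEdges[[as.character(parent)]], e)
    W <- O[[parent]]
    for (se in sibs) W <- W * ip$S[[se]]
    P <- ip$Ps[[e]]
    Lc <- ip$L[[child]]
    tot <- colSums(W * (P %*% Lc))
    tot[tot == 0] <- NA_real_  # numerically impossible profile; flagged NA
    pg <- W[1, ] * as.numeric(P[1, -1, drop = FALSE] %*% Lc[-1, , drop = FALSE])
    pl <- colSums(W[-1, , drop = FALSE] * P[-1, 1]) * Lc[1, ]
    pe <- colSums(W * ((P * masks$expansion) %*% Lc))
    pr <- colSums(W * ((P * masks$reduction) %*% Lc))
    out[e, 1, ] <- pg / tot
    out[e, 2, ] <- pl / tot
    out[e, 3, ] <- pe / tot
    out[e, 4, ] <- pr / tot
    # propagate outside values to the child, rescaled per family
    Oc <- crossprod(P, W)
    cm <- apply(Oc, 2, max)
    cm[cm == 0] <- 1
    O[[child]] <- sweep(Oc, 2, cm, "/")
  }
  out
}

#' Posterior probabilities of genome dynamics events
#'
#' For every family and every tree edge, computes the joint posterior of the
#' (parent, child) family sizes given all leaf counts via inside-outside
#' passes, and reduces it to the posterior probabilities of the four event
#' types: gain (0 -> >=1), loss (>=1 -> 0), expansion (child > parent >= 1)
#' and reduction (parent > child >= 1). Under a rate-category mixture, the
#' per-category posteriors are combined with the per-family category
#' responsibilities.
#'
#' @param model a [FittedBDGModel-class]
#' @param counts integer matrix, families x genomes (genomes matching the
#'   model's tree)
#' @param families optional character vector restricting to a family subset
#' @param truncTol truncation-mass tolerance (see [transitionMatrix()])
#' @return an [EventPosteriors-class]; edges are labelled
#'   `"<parent>-><child>"` using the tree's internal node numbering
#' @export
posteriorEvents <- function(model, counts, families = NULL, truncTol = 1e-9) {
  tree <- model@tree
  validateCountMatrix(counts, tree)
  if (!is.null(families)) {
    missing <- setdiff(families, rownames(counts))
    if (length(missing)) stop("family absent from matrix: ",
                              paste(missing, collapse = ", "))
    counts <- counts[families, , drop = FALSE]
  }
  keep <- rowSums(counts) > 0 | !model@conditioned
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("no observable families to decode")
  M <- model@M
  res <- bdgLogLik(tree, counts, model@rates, M, conditionOnObserved = FALSE,
                   truncTol = truncTol, keepPasses = TRUE)
  ti <- res$ti
  F <- nrow(res$counts)
  K <- length(res$cats)
  nEdges <- nrow(ti$edge)
  bad <- !is.finite(res$perFamily)
  if (any(bad))
    stop("zero likelihood under the model for family: ",
         paste(head(rownames(res$counts)[bad], 5), collapse = ", "),
         "; the profile is impossible under the fitted rates")
  # per-family category responsibilities from the unconditioned likelihoods
  ll <- res$perCategory
  mx <- apply(ll, 1, max)
  wl <- sweep(exp(sweep(ll, 1, mx, "-")), 2, res$weights, "*")
  resp <- wl / rowSums(wl)
  post <- array(0, dim = c(nEdges, 4, F))
  for (k in seq_len(K)) {
    pk <- decodeCategory(res$passes[[k]], ti, M, F)
    pk[is.na(pk)] <- 0
    post <- post + sweep(pk, 3, resp[, k], "*")
  }
  post <- pmin(pmax(post, 0), 1)
  edgeLabel <- paste0(ti$edge[, 1], "->", ti$edge[, 2])
  df <- data.frame(
    family = rep(rownames(res$counts), each = nEdges),
    edge = rep(edgeLabel, F),
    p_gain = as.numeric(post[, 1, ]),
    p_loss = as.numeric(post[, 2, ]),
    p_expansion = as.numeric(post[, 3, ]),
    p_reduction = as.numeric(post[, 4, ]),
    stringsAsFactors = FALSE)
  new("EventPosteriors", posteriors = df,
      nGenomes = length(tree$tip.label), nEdges = as.integer(nEdges))
}

#' Sum event posteriors into expected totals
#'
#' The expected number of events of each type is the sum of the posterior
#' probabilities over all edges and all families in the set.
#'
#' @param posteriors an [EventPosteriors-class]
#' @param nGenomes number of genomes (defaults to the value recorded in
#'   `posteriors`)
#' @param label optional family-set label (e.g. `"DS"`)
#' @param nFamilies number of families the totals are attributed to; defaults
#'   to the number of distinct families present in `posteriors`
#' @return an [EventSummary-class]
#' @export
summarizeEvents <- function(posteriors, nGenomes = NULL, label = "",
                            nFamilies = NULL) {
  p <- posteriors@posteriors
  if (nrow(p) == 0) stop("empty posteriors")
  if (is.null(nGenomes)) nGenomes <- posteriors@nGenomes
  if (is.null(nFamilies)) nFamilies <- length(unique(p$family))
  new("EventSummary",
      gains = sum(p$p_gain), losses = sum(p$p_loss),
      expansions = sum(p$p_expansion), reductions = sum(p$p_reduction),
      nFamilies = as.integer(nFamilies), nGenomes = as.integer(nGenomes),
      label = label)
}

#' Write event posteriors as TSV
#'
#' @param posteriors an [EventPosteriors-class]
#' @param path file path
#' @param header optional '#' comment lines to prepend
#' @export
writeEventPosteriors <- function(posteriors, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(posteriors@posteriors, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
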