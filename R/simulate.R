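# Synthetic ATGC generator: seeded trees, gene-family counts evolved under
# the exact birth-death-gain process with an inflated-rate defense subset,
# logged true per-edge events, and circular chromosome maps with tunable
# defense islands and strand persistence.

#' Simulate a rooted species tree
#'
#' A seeded pure-birth (Yule) tree with exponential waiting times, rescaled so
#' the root-to-tip depth equals `depth`.
#'
#' @param nLeaves number of leaves (>= 2)
#' @param seed RNG seed
#' @param depth root-to-tip depth in time units
#' @return a rooted ultrametric `ape::phylo` with tips `g1..g<n>`
#' @examples
#' simulateTree(5, seed = 42)
#' @export
simulateTree <- function(nLeaves, seed, depth = 0.3) {
  stopifnot(nLeaves >= 2)
  set.seed(seed)
  tree <- ape::rphylo(nLeaves, birth = 1, death = 0)
  tree$tip.label <- paste0("g", seq_len(nLeaves))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h * depth
  tree
}

# Gillespie end state of the chain along one edge for a vector of starts.
simulateBdiEdge <- function(start, t, kappa, lambda, mu) {
  simulateBdiEdgeCpp(as.integer(start), t, kappa, lambda, mu)
}

#' Simulate gene-family evolution on a tree
#'
#' Root counts are drawn from the stationary distribution; along every edge
#' the family size follows the exact event-driven birth-death-gain process.
#' Defense families (the first `defenseFraction` share, with classes drawn
#' from `classMix`) evolve with rates scaled by `defenseMultiplier`. The
#' parent and child state at every edge is logged as ground truth.
#'
#' @param tree rooted `ape::phylo` whose tips are the genomes
#' @param config a [SimConfig-class]; the tree's tip count takes precedence
#'   over `nLeaves`
#' @return a list with `counts` (families x genomes integer matrix),
#'   `annotations` (family -> class), and `truth`: a data.frame (family,
#'   edge, parent_state, child_state, gain, loss, expansion, reduction)
#' @export
simulateFamilies <- function(tree, config) {
  validateSpeciesTree(tree)
  validObject(config)
  set.seed(config@seed)
  nFam <- config@nFamilies
  nDef <- round(config@defenseFraction * nFam)
  famIds <- sprintf("fam%04d", seq_len(nFam))
  classes <- rep("non-defense", nFam)
  if (nDef > 0)
    classes[seq_len(nDef)] <- sample(names(config@classMix), nDef,
                                     replace = TRUE, prob = config@classMix)
  isDef <- classes != "non-defense"
  ti <- treeIndex(tree)
  nEdges <- nrow(ti$edge)
  states <- matrix(NA_integer_, ti$nnode, nFam)
  rootDraw <- function(kappa, lambda, mu, n) {
    if (lambda > 0) rnbinom(n, size = kappa / lambda, prob = 1 - lambda / mu)
    else rpois(n, kappa / mu)
  }
  dm <- config@defenseMultiplier
  states[ti$root, !isDef] <- rootDraw(config@kappa, config@lambda, config@mu,
                                      sum(!isDef))
  if (any(isDef))
    states[ti$root, isDef] <- rootDraw(config@kappa * dm[1],
                                       config@lambda * dm[2],
                                       config@mu * dm[3], sum(isDef))
  # preorder over edges (reverse postorder): parents before children
  for (e in rev(seq_len(nEdges))) {
    parent <- ti$edge[e, 1]; child <- ti$edge[e, 2]; t <- ti$elen[e]
    st <- states[parent, ]
    newSt <- st
    if (any(!isDef))
      newSt[!isDef] <- simulateBdiEdge(st[!isDef], t, config@kappa,
                                       config@lambda, config@mu)
    if (any(isDef))
      newSt[isDef] <- simulateBdiEdge(st[isDef], t, config@kappa * dm[1],
                                      config@lambda * dm[2], config@mu * dm[3])
    states[child, ] <- newSt
  }
  counts <- t(states[seq_len(ti$ntip), , drop = FALSE])
  dimnames(counts) <- list(famIds, ti$tree$tip.label)
  storage.mode(counts) <- "integer"
  edgeLabel <- paste0(ti$edge[, 1], "->", ti$edge[, 2])
  a <- states[ti$edge[, 1], , drop = FALSE]  # nEdges x nFam parent states
  b <- states[ti$edge[, 2], , drop = FALSE]
  truth <- data.frame(
    family = rep(famIds, each = nEdges),
    edge = rep(edgeLabel, nFam),
    parent_state = as.integer(a),
    child_state = as.integer(b),
    gain = as.integer(a == 0 & b >= 1),
    loss = as.integer(a >= 1 & b == 0),
    expansion = as.integer(b > a & a >= 1),
    reduction = as.integer(a > b & b >= 1),
    stringsAsFactors = FALSE)
  list(counts = counts, annotations = setNames(classes, famIds),
       truth = truth)
}

#' Simulate a circular chromosome map for one genome
#'
#' Places every gene copy present in the genome on a circular gene order.
#' With island concentration c, each defense gene is inserted adjacent to an
#' already-placed defense gene with probability c and uniformly otherwise.
#' Strands follow a persistence-p Markov chain along consecutive genes.
#'
#' @param genomeCounts named integer vector: copy number per family in this
#'   genome
#' @param annotations family -> class vector covering the families
#' @param config a [SimConfig-class] (islandConcentration, strandPersistence
#'   and chromosomeSize are used)
#' @param replicon replicon identifier
#' @param seed optional seed override (defaults to the config seed)
#' @return a [ChromosomeMap-class]
#' @export
simulateChromosome <- function(genomeCounts, annotations, config,
                               replicon = "chr1", seed = NULL) {
  validObject(config)
  set.seed(if (is.null(seed)) config@seed else seed)
  present <- genomeCounts[genomeCounts > 0]
  genes <- rep(names(present), present)
  cls <- unname(annotations[genes])
  cls[is.na(cls)] <- "non-defense"
  nFill <- max(0L, config@chromosomeSize - length(genes))
  if (nFill > 0) {
    genes <- c(genes, sprintf("filler%04d", seq_len(nFill)))
    cls <- c(cls, rep("non-defense", nFill))
  }
  nGenes <- length(genes)
  if (nGenes < 1) stop("no genes to place")
  isDef <- cls != "non-defense"
  # non-defense genes in random circular order, then defense genes inserted
  # one at a time: uniformly, or (w.p. islandConcentration) right after a
  # previously placed defense gene
  layout <- if (any(!isDef)) sample(which(!isDef)) else integer(0)
  defIdx <- which(isDef)
  if (length(defIdx)) {
    defIdx <- if (length(defIdx) > 1) sample(defIdx) else defIdx
    placedDef <- integer(0)  # current positions of defense genes in `layout`
    for (g in defIdx) {
      if (length(placedDef) && runif(1) < config@islandConcentration) {
        at <- placedDef[sample.int(length(placedDef), 1)]
      } else {
        at <- sample.int(length(layout) + 1L, 1) - 1L  # insertion slot 0..len
      }
      layout <- append(layout, g, after = at)
      if (length(placedDef))
        placedDef[placedDef > at] <- placedDef[placedDef > at] + 1L
      placedDef <- c(placedDef, at + 1L)
    }
  }
  strand <- character(nGenes)
  strand[1] <- sample(c("+", "-"), 1)
  if (nGenes > 1) {
    keep <- runif(nGenes - 1) < config@strandPersistence
    flips <- cumsum(!keep)
    strand[-1] <- ifelse(flips %% 2 == 0, strand[1],
                         if (strand[1] == "+") "-" else "+")
  }
  ChromosomeMap(replicon = replicon, strand = strand,
                family = genes[layout], geneClass = cls[layout],
                circular = TRUE)
}

#' Simulate a complete synthetic ATGC
#'
#' Composes [simulateTree()], [simulateFamilies()] and (one map per genome)
#' [simulateChromosome()].
#'
#' @param config a [SimConfig-class]
#' @return a list with `tree`, `counts`, `annotations`, `truth`, `maps`
#'   (named list of [ChromosomeMap-class] per genome) and the `config`
#' @examples
#' atgc <- simulateATGC(SimConfig(seed = 3, nLeaves = 4, nFamilies = 100))
#' dim(atgc$counts)
#' @export
simulateATGC <- function(config) {
  validObject(config)
  tree <- simulateTree(config@nLeaves, seed = config@seed,
                       depth = config@treeDepth)
  fam <- simulateFamilies(tree, config)
  maps <- lapply(seq_along(tree$tip.label), function(i) {
    g <- tree$tip.label[i]
    simulateChromosome(fam$counts[, g], fam$annotations, config,
                       replicon = g, seed = config@seed + i)
  })
  names(maps) <- tree$tip.label
  list(tree = tree, counts = fam$counts, annotations = fam$annotations,
       truth = fam$truth, maps = maps, config = config)
}

#' Write / read a simulation config
#'
#' Key-value text serialization of a [SimConfig-class] (seed mandatory).
#'
#' @param config a [SimConfig-class]
#' @param path file path
#' @export
writeSimConfig <- function(config, path) {
  lines <- c("# DefenseFlux simulation config",
             sprintf("seed\t%d", config@seed),
             sprintf("nLeaves\t%d", config@nLeaves),
             sprintf("treeDepth\t%.12g", config@treeDepth),
             sprintf("nFamilies\t%d", config@nFamilies),
             sprintf("defenseFraction\t%.12g", config@defenseFraction),
             sprintf("classMix\t%s",
                     paste(sprintf("%s=%g", names(config@classMix),
                                   config@classMix), collapse = ",")),
             sprintf("kappa\t%.12g", config@kappa),
             sprintf("lambda\t%.12g", config@lambda),
             sprintf("mu\t%.12g", config@mu),
             sprintf("defenseMultiplier\t%s",
                     paste(config@defenseMultiplier, collapse = ",")),
             sprintf("chromosomeSize\t%d", config@chromosomeSize),
             sprintf("islandConcentration\t%.12g", config@islandConcentration),
             sprintf("strandPersistence\t%.12g", config@strandPersistence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(lines, "\t")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  mixParts <- strsplit(strsplit(vals[["classMix"]], ",")[[1]], "=")
  mix <- setNames(as.numeric(vapply(mixParts, `[`, "", 2)),
                  vapply(mixParts, `[`, "", 1))
  SimConfig(seed = as.integer(vals[["seed"]]),
            nLeaves = as.integer(vals[["nLeaves"]]),
            treeDepth = as.numeric(vals[["treeDepth"]]),
            nFamilies = as.integer(vals[["nFamilies"]]),
            defenseFraction = as.numeric(vals[["defenseFraction"]]),
            classMix = mix,
            kappa = as.numeric(vals[["kappa"]]),
            lambda = as.numeric(vals[["lambda"]]),
            mu = as.numeric(vals[["mu"]]),
            defenseMultiplier = as.numeric(strsplit(vals[["defenseMultiplier"]], ",")[[1]]),
            chromosomeSize = as.integer(vals[["chromosomeSize"]]),
            islandConcentration = as.numeric(vals[["islandConcentration"]]),
            strandPersistence = as.numeric(vals[["strandPersistence"]]))
}
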