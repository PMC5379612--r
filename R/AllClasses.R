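#' @import methods
#' @importFrom stats median optim optimize qgamma dnbinom dpois rnbinom rpois
#'   chisq.test t.test pgamma setNames runif rexp cov cor var sd quantile
#' @importFrom utils read.delim write.table packageVersion
#' @useDynLib DefenseFlux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Birth-death-gain model rates
#'
#' Parameters of the linear birth-death-immigration process that models the
#' size of a gene family along a species tree: a family of size \eqn{n} loses
#' a copy at rate \eqn{n\mu} and acquires one at rate \eqn{\kappa + n\lambda},
#' where \eqn{\kappa} is the gain (immigration) rate per family, \eqn{\lambda}
#' the per-copy duplication rate and \eqn{\mu} the per-copy loss rate.
#'
#' Rate heterogeneity across families is modelled by `nCategories`
#' equal-probability discrete gamma categories (shape `categoryShape`, mean 1)
#' whose multipliers scale all three rates jointly.  Optional per-edge
#' multipliers (named by edge index in the tree's edge matrix) scale the rates
#' on individual branches.
#'
#' @slot kappa gain rate per family per unit time (>= 0)
#' @slot lambda duplication rate per gene copy per unit time (>= 0)
#' @slot mu loss rate per gene copy per unit time (>= 0)
#' @slot categoryShape gamma shape for the discrete rate categories
#'   (`NA_real_` when `nCategories == 1`)
#' @slot nCategories number of equal-probability rate categories (1..4)
#' @slot edgeMultipliers numeric vector of per-edge scale factors (> 0),
#'   length 0 when uniform across edges
#' @export
setClass("BDGRates",
  representation(
    kappa = "numeric", lambda = "numeric", mu = "numeric",
    categoryShape = "numeric", nCategories = "integer",
    edgeMultipliers = "numeric"
  ),
  prototype(
    kappa = 0.5, lambda = 0.1, mu = 1.0,
    categoryShape = NA_real_, nCategories = 1L,
    edgeMultipliers = numeric(0)
  )
)

setValidity("BDGRates", function(object) {
  msg <- character(0)
  if (length(object@kappa) != 1 || object@kappa < 0) msg <- c(msg, "kappa must be a single non-negative number")
  if (length(object@lambda) != 1 || object@lambda < 0) msg <- c(msg, "lambda must be a single non-negative number")
  if (length(object@mu) != 1 || object@mu < 0) msg <- c(msg, "mu must be a single non-negative number")
  if (object@nCategories < 1L || object@nCategories > 4L) msg <- c(msg, "nCategories must be in 1..4")
  if (object@nCategories > 1L && (is.na(object@categoryShape) || object@categoryShape <= 0))
    msg <- c(msg, "categoryShape must be positive when nCategories > 1")
  if (length(object@edgeMultipliers) && any(object@edgeMultipliers <= 0))
    msg <- c(msg, "edge multipliers must be positive")
  if (length(msg)) msg else TRUE
})

#' Constructor for [BDGRates-class]
#'
#' @param kappa,lambda,mu model rates (see the class documentation)
#' @param categoryShape gamma shape of the discrete rate categories
#' @param nCategories number of equal-probability categories (1..4)
#' @param edgeMultipliers optional per-edge positive scale factors
#' @return a validated [BDGRates-class] object
#' @examples
#' BDGRates(kappa = 0.4, lambda = 0.2, mu = 1)
#' @export
BDGRates <- function(kappa, lambda, mu, categoryShape = NA_real_,
                     nCategories = 1L, edgeMultipliers = numeric(0)) {
  new("BDGRates", kappa = as.numeric(kappa), lambda = as.numeric(lambda),
      mu = as.numeric(mu), categoryShape = as.numeric(categoryShape),
      nCategories = as.integer(nCategories),
      edgeMultipliers = as.numeric(edgeMultipliers))
}

#' Fitted phylogenetic birth-death-gain model
#'
#' @slot tree rooted `ape::phylo` species tree
#' @slot rates fitted [BDGRates-class]
#' @slot logLik maximized total log-likelihood
#' @slot trace data.frame with one row per fitting round
#'   (round, description, logLik)
#' @slot M state-space truncation bound used
#' @slot conditioned logical; likelihood conditioned on families being
#'   observed (non-all-zero)
#' @slot converged logical
#' @export
setClass("FittedBDGModel",
  representation(
    tree = "ANY", rates = "BDGRates", logLik = "numeric",
    trace = "data.frame", M = "integer", conditioned = "logical",
    converged = "logical"
  )
)

setValidity("FittedBDGModel", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo object")
  if (!is.finite(object@logLik)) msg <- c(msg, "logLik must be finite")
  if (nrow(object@trace) > 1 && any(diff(object@trace$logLik) < -1e-6))
    msg <- c(msg, "trace log-likelihood must be non-decreasing across rounds")
  if (length(msg)) msg else TRUE
})

#' Posterior event probabilities per family and edge
#'
#' For every (family, edge) pair, the posterior probability, given the whole
#' phyletic profile, that the parent/child family sizes (a, b) fall into each
#' of four patterns: gain (a = 0, b >= 1), loss (a >= 1, b = 0), expansion
#' (b > a >= 1) and reduction (a > b >= 1).
#'
#' @slot posteriors data.frame with columns family, edge, p_gain, p_loss,
#'   p_expansion, p_reduction
#' @slot nGenomes number of genomes (tree tips)
#' @slot nEdges number of tree edges
#' @export
setClass("EventPosteriors",
  representation(posteriors = "data.frame", nGenomes = "integer",
                 nEdges = "integer")
)

setValidity("EventPosteriors", function(object) {
  p <- object@posteriors
  need <- c("family", "edge", "p_gain", "p_loss", "p_expansion", "p_reduction")
  if (!all(need %in% names(p))) return("missing posterior columns")
  v <- as.matrix(p[, need[-(1:2)]])
  if (any(v < -1e-9 | v > 1 + 1e-9)) return("posteriors must lie in [0, 1]")
  if (any(p$p_gain + p$p_loss > 1 + 1e-6)) return("p_gain + p_loss must be <= 1")
  if (any(p$p_gain + p$p_expansion > 1 + 1e-6)) return("p_gain + p_expansion must be <= 1")
  TRUE
})

#' Expected event totals over a family set
#'
#' @slot gains,losses,expansions,reductions expected event counts summed over
#'   edges and families (sums of posterior probabilities)
#' @slot nFamilies number of families in the summed set
#' @slot nGenomes number of genomes
#' @slot label family-set label (e.g. "DS" or "all")
#' @export
setClass("EventSummary",
  representation(gains = "numeric", losses = "numeric", expansions = "numeric",
                 reductions = "numeric", nFamilies = "integer",
                 nGenomes = "integer", label = "character"),
  prototype(label = "")
)

setValidity("EventSummary", function(object) {
  tot <- c(object@gains, object@losses, object@expansions, object@reductions)
  if (any(tot < -1e-9)) return("event totals must be non-negative")
  TRUE
})

#' Ordered, stranded gene map of one replicon
#'
#' @slot replicon replicon identifier
#' @slot circular logical; circular replicon
#' @slot strand character vector in {"+", "-"}, one per gene in chromosomal
#'   order (0-based index = position in this vector minus 1)
#' @slot family gene family identifier per gene
#' @slot geneClass defense class per gene ("non-defense" for the rest)
#' @export
setClass("ChromosomeMap",
  representation(replicon = "character", circular = "logical",
                 strand = "character", family = "character",
                 geneClass = "character")
)

defenseClasses <- function() c("RM", "TA", "CRISPR-Cas", "Abi", "other-defense")

validClasses <- function() c(defenseClasses(), "non-defense")

setValidity("ChromosomeMap", function(object) {
  n <- length(object@strand)
  if (n < 1) return("a chromosome map needs at least one gene")
  if (length(object@family) != n || length(object@geneClass) != n)
    return("strand, family and geneClass must have equal length")
  if (!all(object@strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  if (!all(object@geneClass %in% validClasses()))
    return("gene classes must come from the closed vocabulary")
  TRUE
})

#' Constructor for [ChromosomeMap-class]
#' @param replicon replicon id
#' @param strand character vector of "+"/"-"
#' @param family gene family ids, same length as `strand`
#' @param geneClass defense classes, same length as `strand`
#' @param circular logical, default `TRUE`
#' @return a validated [ChromosomeMap-class]
#' @export
ChromosomeMap <- function(replicon, strand, family, geneClass, circular = TRUE) {
  new("ChromosomeMap", replicon = as.character(replicon),
      circular = isTRUE(circular), strand = as.character(strand),
      family = as.character(family), geneClass = as.character(geneClass))
}

#' Maximal runs of co-directed genes
#'
#' @slot members list of integer vectors; each vector holds the 0-based gene
#'   indices of one directon, in chromosomal order
#' @slot strands strand of each directon
#' @slot defense logical; directon contains at least one defense gene
#' @slot nGenes number of genes in the underlying map
#' @slot circular circularity inherited from the map
#' @export
setClass("DirectonSet",
  representation(members = "list", strands = "character", defense = "logical",
                 nGenes = "integer", circular = "logical")
)

setValidity("DirectonSet", function(object) {
  idx <- sort(unlist(object@members))
  if (!identical(as.integer(idx), seq_len(object@nGenes) - 1L))
    return("directons must partition the gene indices 0..n-1")
  if (length(object@strands) != length(object@members) ||
      length(object@defense) != length(object@members))
    return("per-directon vectors must match the number of directons")
  TRUE
})

#' Result of a co-localization randomization test
#'
#' @slot observed observed median nearest-neighbour distance (index units)
#' @slot p one-sided permutation p-value, add-one corrected
#' @slot nullMedians null distribution of the statistic
#' @slot nReps number of randomizations
#' @slot seed RNG seed used
#' @slot level "gene" or "directon"
#' @slot degenerate logical; test was degenerate (e.g. all units are defense)
#' @export
setClass("ColocalizationResult",
  representation(observed = "numeric", p = "numeric", nullMedians = "numeric",
                 nReps = "integer", seed = "integer", level = "character",
                 degenerate = "logical")
)

setValidity("ColocalizationResult", function(object) {
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  if (!object@level %in% c("gene", "directon")) return("level must be gene or directon")
  TRUE
})

#' Configuration of the synthetic ATGC generator
#'
#' Defaults emulate a mid-sized ATGC: 10 genomes, 1000 gene families of which
#' 5% belong to defense systems, base rates kappa = 0.5, lambda = 0.1,
#' mu = 1.0 (loss-dominated, as observed in prokaryote gene-content
#' evolution), a 1.5-fold rate multiplier on the defense subset, and circular
#' chromosomes with strand persistence 0.8.
#'
#' @slot nLeaves number of genomes (tree tips)
#' @slot treeDepth root-to-tip depth of the simulated tree (time units)
#' @slot nFamilies number of gene families
#' @slot defenseFraction fraction of families assigned to defense classes
#' @slot classMix named probabilities over the defense classes
#' @slot kappa,lambda,mu base model rates
#' @slot defenseMultiplier multipliers applied to (kappa, lambda, mu) for
#'   defense families; scalar recycles to all three
#' @slot chromosomeSize number of gene slots per circular chromosome; genes
#'   above the genome's gene count are fillers drawn as non-defense
#' @slot islandConcentration probability in [0,1] that a defense gene is
#'   placed adjacent to an already-placed defense gene
#' @slot strandPersistence probability in [0,1] that a gene keeps the
#'   previous gene's strand
#' @slot seed RNG seed (mandatory)
#' @export
setClass("SimConfig",
  representation(
    nLeaves = "integer", treeDepth = "numeric", nFamilies = "integer",
    defenseFraction = "numeric", classMix = "numeric",
    kappa = "numeric", lambda = "numeric", mu = "numeric",
    defenseMultiplier = "numeric", chromosomeSize = "integer",
    islandConcentration = "numeric", strandPersistence = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nLeaves < 2) msg <- c(msg, "nLeaves must be >= 2")
  if (object@treeDepth <= 0) msg <- c(msg, "treeDepth must be positive")
  if (object@nFamilies < 1) msg <- c(msg, "nFamilies must be >= 1")
  if (object@defenseFraction < 0 || object@defenseFraction > 1)
    msg <- c(msg, "defenseFraction must lie in [0, 1]")
  if (any(c(object@kappa, object@lambda, object@mu) < 0))
    msg <- c(msg, "rates must be non-negative")
  if (length(object@defenseMultiplier) != 3 || any(object@defenseMultiplier <= 0))
    msg <- c(msg, "defenseMultiplier must be three positive numbers")
  if (object@lambda >= object@mu)
    msg <- c(msg, "lambda must be < mu for stationary initialization")
  if (object@lambda * object@defenseMultiplier[2] >= object@mu * object@defenseMultiplier[3])
    msg <- c(msg, "defense-scaled lambda must stay < defense-scaled mu")
  if (object@islandConcentration < 0 || object@islandConcentration > 1)
    msg <- c(msg, "islandConcentration must lie in [0, 1]")
  if (object@strandPersistence < 0 || object@strandPersistence > 1)
    msg <- c(msg, "strandPersistence must lie in [0, 1]")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (abs(sum(object@classMix) - 1) > 1e-9 ||
      !all(names(object@classMix) %in% defenseClasses()))
    msg <- c(msg, "classMix must be probabilities over the defense classes summing to 1")
  if (length(msg)) msg else TRUE
})

#' Constructor for [SimConfig-class]
#'
#' @param nLeaves,treeDepth,nFamilies,defenseFraction,classMix see class slots
#' @param kappa,lambda,mu,defenseMultiplier,chromosomeSize see class slots
#' @param islandConcentration,strandPersistence,seed see class slots
#' @return a validated [SimConfig-class]
#' @examples
#' SimConfig(seed = 1, nLeaves = 8, nFamilies = 200)
#' @export
SimConfig <- function(seed,
                      nLeaves = 10L, treeDepth = 0.3, nFamilies = 1000L,
                      defenseFraction = 0.05,
                      classMix = c("TA" = 0.30, "RM" = 0.20,
                                   "CRISPR-Cas" = 0.15, "Abi" = 0.15,
                                   "other-defense" = 0.20),
                      kappa = 0.5, lambda = 0.1, mu = 1.0,
                      defenseMultiplier = c(1.5, 1.5, 1.5),
                      chromosomeSize = 0L,
                      islandConcentration = 0, strandPersistence = 0.8) {
  if (length(defenseMultiplier) == 1) defenseMultiplier <- rep(defenseMultiplier, 3)
  new("SimConfig", nLeaves = as.integer(nLeaves), treeDepth = treeDepth,
      nFamilies = as.integer(nFamilies), defenseFraction = defenseFraction,
      classMix = classMix, kappa = kappa, lambda = lambda, mu = mu,
      defenseMultiplier = as.numeric(defenseMultiplier),
      chromosomeSize = as.integer(chromosomeSize),
      islandConcentration = islandConcentration,
      strandPersistence = strandPersistence, seed = as.integer(seed))
}
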