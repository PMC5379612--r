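# Directons and randomization tests for chromosomal co-localization of
# defense genes and of inferred gain/loss events. Distances are in
# gene-index units (the randomization samples genes, so index units make the
# null exchangeable); circular replicons use the minimum-arc distance.

#' Build directons from a chromosome map
#'
#' A directon is a maximal run of consecutive co-directed genes. On circular
#' replicons the first and last run merge when co-directed. A directon is
#' defense-flagged if at least one of its genes belongs to a defense system.
#'
#' @param map a [ChromosomeMap-class]
#' @return a [DirectonSet-class]
#' @examples
#' m <- ChromosomeMap("chr", c("+", "+", "-", "+"), paste0("f", 1:4),
#'                    rep("non-defense", 4), circular = FALSE)
#' directons(buildDirectons(m))
#' @export
buildDirectons <- function(map) {
  s <- map@strand
  n <- length(s)
  runEnd <- which(s != c(s[-1], s[1]))  # last index (1-based) of each run
  if (length(runEnd) == 0) {
    # single strand throughout: one directon (circular) or one linear run
    members <- list(seq_len(n) - 1L)
  } else {
    bounds <- c(runEnd, if (!map@circular && runEnd[length(runEnd)] != n) n)
    members <- list()
    start <- runEnd[length(runEnd)] + 1L  # first run begins after the last break
    if (map@circular) {
      if (start <= n) {
        wrap <- c(seq(start, n), seq_len(runEnd[1]))
      } else {
        wrap <- seq_len(runEnd[1])
      }
      members[[1]] <- as.integer(wrap - 1L)
      prev <- runEnd[1]
      for (b in runEnd[-1]) {
        members[[length(members) + 1]] <- as.integer(seq(prev + 1L, b) - 1L)
        prev <- b
      }
    } else {
      prev <- 0L
      for (b in bounds) {
        members[[length(members) + 1]] <- as.integer(seq(prev + 1L, b) - 1L)
        prev <- b
      }
    }
  }
  strands <- vapply(members, function(m) s[m[1] + 1L], "")
  defense <- vapply(members, function(m)
    any(map@geneClass[m + 1L] != "non-defense"), NA)
  new("DirectonSet", members = members, strands = strands, defense = defense,
      nGenes = as.integer(n), circular = map@circular)
}

#' Median nearest-neighbour distance
#'
#' For each position, the distance (in index units; minimum arc when
#' circular) to the closest other position; returns the median (the mean of
#' the two central order statistics for even counts).
#'
#' @param positions integer vector of 0-based positions (>= 2 of them)
#' @param n total number of positions on the replicon
#' @param circular logical
#' @return the median nearest-neighbour distance
#' @examples
#' nearestNeighborMedian(c(0, 50), 100, circular = TRUE)  # both arcs are 50
#' @export
nearestNeighborMedian <- function(positions, n, circular) {
  k <- length(positions)
  if (k < 2) stop("need at least 2 positions")
  p <- sort(as.integer(positions))
  gapNext <- c(diff(p), if (circular) n - p[k] + p[1] else Inf)
  gapPrev <- c(if (circular) n - p[k] + p[1] else Inf, diff(p))
  median(pmin(gapNext, gapPrev))
}

# shared permutation machinery: observed statistic vs nReps draws of
# equal-sized uniform without-replacement samples from a candidate pool
permutationP <- function(observedPositions, pool, n, circular, nReps, seed,
                         level) {
  k <- length(observedPositions)
  degenerate <- k >= length(pool)
  observed <- nearestNeighborMedian(observedPositions, n, circular)
  set.seed(seed)
  if (degenerate) {
    return(new("ColocalizationResult", observed = observed, p = 1,
               nullMedians = numeric(0), nReps = as.integer(nReps),
               seed = as.integer(seed), level = level, degenerate = TRUE))
  }
  nullMedians <- vapply(seq_len(nReps), function(i)
    nearestNeighborMedian(sample(pool, k), n, circular), numeric(1))
  p <- (1 + sum(nullMedians <= observed)) / (1 + nReps)
  new("ColocalizationResult", observed = observed, p = p,
      nullMedians = nullMedians, nReps = as.integer(nReps),
      seed = as.integer(seed), level = level, degenerate = FALSE)
}

#' Randomization test for defense-gene co-localization
#'
#' Tests whether defense units (genes, or directons containing a defense
#' gene) sit closer together on the chromosome than expected by chance: the
#' observed median nearest-neighbour distance is compared against `nReps`
#' equal-sized uniform without-replacement samples of units. One-sided
#' (clustering = smaller median), with the add-one correction
#' p = (1 + #\{null <= observed\}) / (1 + nReps).
#'
#' @param map a [ChromosomeMap-class]
#' @param level `"gene"` or `"directon"`
#' @param nReps number of randomizations (default 10000)
#' @param seed RNG seed, recorded in the result
#' @return a [ColocalizationResult-class]
#' @export
colocalizationTest <- function(map, level = c("gene", "directon"),
                               nReps = 10000L, seed = 1L) {
  level <- match.arg(level)
  if (level == "gene") {
    units <- length(map@strand)
    def <- which(map@geneClass != "non-defense") - 1L
    circular <- map@circular
  } else {
    ds <- buildDirectons(map)
    units <- length(ds@members)
    def <- which(ds@defense) - 1L
    circular <- map@circular
  }
  if (length(def) < 2) stop("need at least 2 defense units at the ", level, " level")
  permutationP(def, 0:(units - 1L), units, circular, nReps, seed, level)
}

#' Randomization test for event co-localization among defense genes
#'
#' Tests whether genes with inferred gain/loss events on terminal branches
#' cluster among the defense genes: the null resamples positions from all
#' defense genes (not from all genes).
#'
#' @param eventPositions 0-based positions of event genes (must be a subset
#'   of `defensePositions`)
#' @param defensePositions 0-based positions of all defense genes
#' @param map the [ChromosomeMap-class] the positions refer to
#' @param level `"gene"` or `"directon"`; at the directon level positions are
#'   translated to directon indices
#' @param nReps,seed as in [colocalizationTest()]
#' @return a [ColocalizationResult-class]
#' @export
eventColocalizationTest <- function(eventPositions, defensePositions, map,
                                    level = c("gene", "directon"),
                                    nReps = 10000L, seed = 1L) {
  level <- match.arg(level)
  if (!all(eventPositions %in% defensePositions))
    stop("event positions must be a subset of defense positions")
  if (length(eventPositions) < 2) stop("need at least 2 event positions")
  if (level == "gene") {
    n <- length(map@strand)
    permutationP(eventPositions, defensePositions, n, map@circular, nReps,
                 seed, level)
  } else {
    ds <- buildDirectons(map)
    geneToDirecton <- integer(ds@nGenes)
    for (i in seq_along(ds@members))
      geneToDirecton[ds@members[[i]] + 1L] <- i - 1L
    ev <- unique(geneToDirecton[eventPositions + 1L])
    def <- unique(geneToDirecton[defensePositions + 1L])
    if (length(ev) < 2) stop("events map to fewer than 2 directons")
    permutationP(ev, def, length(ds@members), map@circular, nReps, seed, level)
  }
}

#' Write co-localization results as TSV
#'
#' @param results named list of [ColocalizationResult-class] (names =
#'   replicon IDs)
#' @param path file path
#' @param header optional '#' comment lines
#' @export
writeColocalizationResults <- function(results, path, header = character(0)) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(replicon = nm, level = r@level, observed = r@observed,
               p = r@p, n_reps = r@nReps, seed = r@seed,
               degenerate = r@degenerate, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
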