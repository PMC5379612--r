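# show methods and accessors

setMethod("show", "BDGRates", function(object) {
  cat("Birth-death-gain rates\n")
  cat(sprintf("  kappa (gain) = %.4g  lambda (duplication) = %.4g  mu (loss) = %.4g\n",
              object@kappa, object@lambda, object@mu))
  if (object@nCategories > 1L)
    cat(sprintf("  %d discrete gamma rate categories, shape = %.4g\n",
                object@nCategories, object@categoryShape))
  if (length(object@edgeMultipliers))
    cat(sprintf("  per-edge multipliers on %d edges (range %.3g..%.3g)\n",
                length(object@edgeMultipliers),
                min(object@edgeMultipliers), max(object@edgeMultipliers)))
  invisible(object)
})

setMethod("show", "FittedBDGModel", function(object) {
  cat(sprintf("Fitted birth-death-gain model (%d tips, %d edges, M = %d)\n",
              length(object@tree$tip.label), nrow(object@tree$edge), object@M))
  cat(sprintf("  log-likelihood = %.4f  (%s, %d fitting rounds)\n",
              object@logLik,
              if (object@converged) "converged" else "NOT converged",
              nrow(object@trace)))
  show(object@rates)
  invisible(object)
})

setMethod("show", "EventPosteriors", function(object) {
  cat(sprintf("Event posteriors: %d families x %d edges (%d genomes)\n",
              length(unique(object@posteriors$family)), object@nEdges,
              object@nGenomes))
  invisible(object)
})

setMethod("show", "EventSummary", function(object) {
  cat(sprintf("Event summary%s: %d families, %d genomes\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              object@nFamilies, object@nGenomes))
  cat(sprintf("  gains %.2f  losses %.2f  expansions %.2f  reductions %.2f\n",
              object@gains, object@losses, object@expansions, object@reductions))
  invisible(object)
})

setMethod("show", "ChromosomeMap", function(object) {
  cat(sprintf("ChromosomeMap %s: %d genes (%s), %d defense\n",
              object@replicon, length(object@strand),
              if (object@circular) "circular" else "linear",
              sum(object@geneClass != "non-defense")))
  invisible(object)
})

setMethod("show", "DirectonSet", function(object) {
  cat(sprintf("DirectonSet: %d directons over %d genes, %d defense-flagged\n",
              length(object@members), object@nGenes, sum(object@defense)))
  invisible(object)
})

setMethod("show", "ColocalizationResult", function(object) {
  cat(sprintf("Co-localization test (%s level): observed median = %.3g, p = %.4g (%d reps, seed %d)%s\n",
              object@level, object@observed, object@p, object@nReps,
              object@seed, if (object@degenerate) " [degenerate]" else ""))
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d genomes, %d families (%.0f%% defense), seed %d\n",
              object@nLeaves, object@nFamilies, 100 * object@defenseFraction,
              object@seed))
  cat(sprintf("  rates kappa=%.3g lambda=%.3g mu=%.3g, defense multiplier (%.3g, %.3g, %.3g)\n",
              object@kappa, object@lambda, object@mu,
              object@defenseMultiplier[1], object@defenseMultiplier[2],
              object@defenseMultiplier[3]))
  invisible(object)
})

#' Accessors
#'
#' Small accessor helpers for the package's S4 containers.
#'
#' @param object an object of the documented class
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
bdgRates <- function(object) {
  stopifnot(is(object, "FittedBDGModel"))
  object@rates
}

#' @rdname accessors
#' @export
fittingTrace <- function(object) {
  stopifnot(is(object, "FittedBDGModel"))
  object@trace
}

#' @describeIn accessors maximized log-likelihood of a fitted model
#' @export
setMethod("logLik", "FittedBDGModel", function(object) object@logLik)

#' @rdname accessors
#' @export
eventTable <- function(object) {
  stopifnot(is(object, "EventPosteriors"))
  object@posteriors
}

#' @rdname accessors
#' @export
eventTotals <- function(object) {
  stopifnot(is(object, "EventSummary"))
  c(gains = object@gains, losses = object@losses,
    expansions = object@expansions, reductions = object@reductions)
}

#' @rdname accessors
#' @export
nFamilies <- function(object) {
  stopifnot(is(object, "EventSummary"))
  object@nFamilies
}

#' @rdname accessors
#' @export
nGenomes <- function(object) {
  stopifnot(is(object, "EventSummary"))
  object@nGenomes
}

#' @rdname accessors
#' @export
directons <- function(object) {
  stopifnot(is(object, "DirectonSet"))
  object@members
}

#' @rdname accessors
#' @export
pValue <- function(object) {
  stopifnot(is(object, "ColocalizationResult"))
  object@p
}
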