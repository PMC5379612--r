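# Normalized event rates, defense-vs-all relative-rate tables, flux
# classification, and the composition / rate-excess tests.

#' Normalize event totals into per-family per-genome rates
#'
#' Divides each expected event total by (number of families x number of
#' genomes), giving dimensionless rates in events per family (COG) per
#' genome, plus the combined genome-dynamics (GDE) rate.
#'
#' @param summary an [EventSummary-class]
#' @return a named numeric vector with elements gain, loss, expansion,
#'   reduction, all_gde, and attributes `nFamilies`, `nGenomes`, `label`
#' @examples
#' s <- new("EventSummary", gains = 120, losses = 0, expansions = 0,
#'          reductions = 0, nFamilies = 300L, nGenomes = 10L, label = "toy")
#' normalizeEvents(s)["gain"]  # 0.04 events per family per genome
#' @export
normalizeEvents <- function(summary) {
  if (summary@nFamilies <= 0 || summary@nGenomes <= 0)
    stop("nFamilies and nGenomes must be positive")
  denom <- summary@nFamilies * summary@nGenomes
  r <- c(gain = summary@gains, loss = summary@losses,
         expansion = summary@expansions, reduction = summary@reductions) / denom
  r <- c(r, all_gde = sum(r))
  attr(r, "nFamilies") <- summary@nFamilies
  attr(r, "nGenomes") <- summary@nGenomes
  attr(r, "label") <- summary@label
  r
}

#' Defense-over-all relative rates
#'
#' For each event type (and the combined GDE rate), the defense-system rate
#' per family divided by the all-gene rate per family. Zero all-gene rates
#' make the ratio undefined (`NA`), never 0 or infinity.
#'
#' @param ds,all normalized rate vectors from [normalizeEvents()]
#' @param atgc,genus row identifiers
#' @return a one-row data.frame with the five ratio columns
#' @export
relativeRates <- function(ds, all, atgc = "ATGC", genus = "") {
  ratio <- function(x, y) if (is.na(y) || y <= 0) NA_real_ else x / y
  data.frame(atgc = atgc, genus = genus,
             gain_ratio = ratio(ds["gain"], all["gain"]),
             loss_ratio = ratio(ds["loss"], all["loss"]),
             expansion_ratio = ratio(ds["expansion"], all["expansion"]),
             reduction_ratio = ratio(ds["reduction"], all["reduction"]),
             all_gde_ratio = ratio(ds["all_gde"], all["all_gde"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

ratioColumns <- function() c("gain_ratio", "loss_ratio", "expansion_ratio",
                             "reduction_ratio", "all_gde_ratio")

#' Column means of a relative-rate table
#'
#' @param table a relative-rate data.frame (see [loadTable1()])
#' @return named numeric vector of arithmetic means of the five ratio
#'   columns; undefined (`NA`) cells are excluded, with a message reporting
#'   how many
#' @examples
#' round(meanRatios(loadTable1()), 2)
#' @export
meanRatios <- function(table) {
  if (nrow(table) == 0) stop("empty table")
  cols <- intersect(ratioColumns(), names(table))
  nNA <- sum(is.na(table[, cols]))
  if (nNA > 0) message(nNA, " undefined ratio cells excluded from the means")
  colMeans(table[, cols, drop = FALSE], na.rm = TRUE)
}

#' Count rows exceeding a threshold
#'
#' @param table a relative-rate data.frame
#' @param column column name
#' @param threshold numeric; rows with value strictly greater are counted
#' @return integer count
#' @examples
#' countExceeding(loadTable1(), "gain_ratio", 1)
#' @export
countExceeding <- function(table, column, threshold) {
  if (!column %in% names(table)) stop("no such column: ", column)
  sum(table[[column]] > threshold, na.rm = TRUE)
}

#' Classify ATGCs into high / average / low flux
#'
#' Rows are ranked by the combined (all-GDE) defense-over-all ratio; the top
#' floor(N/4) are "high", the bottom floor(N/4) "low", the rest "average".
#' Ties are broken deterministically by ATGC ID (ascending), so permuting the
#' row order never changes the assignment.
#'
#' @param table a relative-rate data.frame with >= 4 rows
#' @return a data.frame (atgc, all_gde_ratio, flux_class) plus attributes
#'   `cutpoints` (the quartile boundary values)
#' @examples
#' table(classifyFlux(loadTable1())$flux_class)
#' @export
classifyFlux <- function(table) {
  n <- nrow(table)
  if (n < 4) stop("need at least 4 rows to form quartiles")
  k <- n %/% 4
  ord <- order(-table$all_gde_ratio, table$atgc)
  cls <- rep("average", n)
  cls[ord[seq_len(k)]] <- "high"
  cls[ord[seq(n - k + 1, n)]] <- "low"
  out <- data.frame(atgc = table$atgc, all_gde_ratio = table$all_gde_ratio,
                    flux_class = cls, stringsAsFactors = FALSE)
  attr(out, "cutpoints") <- c(low = table$all_gde_ratio[ord[n - k + 1]],
                              high = table$all_gde_ratio[ord[k]])
  out
}

#' Chi-square comparison of event-type composition
#'
#' Builds a 2 x 4 contingency table of expected event counts (rounded to the
#' nearest integer, since posterior totals are expected counts) for
#' {defense, all-minus-defense} x {gain, loss, expansion, reduction} and
#' applies the chi-square test of homogeneity (df = 3).
#'
#' @param ds,all [EventSummary-class] objects; `all` must contain `ds`
#' @return a list with `statistic`, `p.value`, `table` and `lowExpected`
#'   (TRUE when any expected cell < 1, flagging an unreliable test)
#' @export
compareEventComposition <- function(ds, all) {
  dsRow <- round(eventTotals(ds))
  allRow <- round(eventTotals(all))
  rest <- allRow - dsRow
  if (any(rest < 0)) stop("'all' must contain the defense totals")
  tab <- rbind(DS = dsRow, rest = rest)
  if (sum(dsRow) == 0 || sum(rest) == 0) stop("both family sets need positive totals")
  suppressWarnings(ct <- chisq.test(tab))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value),
       table = tab, lowExpected = any(ct$expected < 1))
}

#' Welch test for rate excess across ATGCs
#'
#' Compares log-transformed defense rates against log-transformed all-gene
#' rates across ATGCs with the Welch two-sample t-test (two-sided).
#' Non-positive values are dropped pairwise with a warning.
#'
#' @param dsRates,allRates numeric vectors of per-ATGC normalized rates for
#'   one event type, same length
#' @return a list with `p.value`, `statistic` and `nUsed`
#' @export
testRateExcess <- function(dsRates, allRates) {
  if (length(dsRates) != length(allRates)) stop("rate vectors must be paired per ATGC")
  ok <- dsRates > 0 & allRates > 0 & is.finite(dsRates) & is.finite(allRates)
  if (any(!ok)) warning(sum(!ok), " non-positive rate pairs dropped")
  if (sum(ok) < 3) stop("fewer than 3 usable ATGC pairs")
  tt <- t.test(log(dsRates[ok]), log(allRates[ok]), var.equal = FALSE)
  list(p.value = unname(tt$p.value), statistic = unname(tt$statistic),
       nUsed = sum(ok))
}
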