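# Pipeline orchestration: write a complete synthetic dataset, run the full
# analysis (fit -> events -> normalization -> relative rates -> PCA ->
# co-localization), and summarize the packaged relative-rate table.

outputHeader <- function(seed, configChecksum = NA_character_) {
  c(sprintf("DefenseFlux %s", as.character(packageVersion("DefenseFlux"))),
    sprintf("seed: %s", seed),
    sprintf("config_checksum: %s", configChecksum))
}

configChecksum <- function(path) {
  unname(tools::md5sum(path))
}

#' Write a complete synthetic ATGC dataset
#'
#' Simulates an ATGC under `config` and writes six files to `dir`: the config
#' (`config.txt`), tree (`tree.nwk`), count matrix (`counts.tsv`), family
#' annotations (`annotations.tsv`), per-genome gene maps (`genemap.tsv`) and
#' the true per-edge events (`truth.tsv`). Re-running with the same config
#' reproduces identical files.
#'
#' @param config a [SimConfig-class]
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
runSimulate <- function(config, dir) {
  validObject(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atgc <- simulateATGC(config)
  writeSimConfig(config, file.path(dir, "config.txt"))
  ape::write.tree(atgc$tree, file.path(dir, "tree.nwk"))
  writeCountMatrix(atgc$counts, file.path(dir, "counts.tsv"))
  writeAnnotations(atgc$annotations, file.path(dir, "annotations.tsv"))
  writeGeneMaps(atgc$maps, file.path(dir, "genemap.tsv"))
  write.table(atgc$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full gain/loss analysis on one dataset
#'
#' Fits the birth-death-gain model on all families, decodes event posteriors
#' for the defense subset and for all families, normalizes the totals into
#' per-family per-genome rates, derives the defense-over-all relative-rate
#' row, and runs the gene- and directon-level co-localization tests on each
#' replicon. Results are written as TSV files (each carrying a header with
#' the seed and config checksum) and returned as a list.
#'
#' @param treePath,countsPath,annotationsPath,geneMapPath input files
#'   (`geneMapPath` may be `NULL` to skip the co-localization tests)
#' @param outDir output directory
#' @param atgcId label for the relative-rate row
#' @param fit a [fitConfig()] list
#' @param nReps randomizations for the co-localization tests
#' @param seed seed recorded in outputs and used for the randomization tests
#' @return a list with `model`, `summaries`, `rates`, `relativeRates`,
#'   `composition`, `colocalization`
#' @export
runAnalyze <- function(treePath, countsPath, annotationsPath,
                       geneMapPath = NULL, outDir, atgcId = "ATGC",
                       fit = fitConfig(), nReps = 1000L, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tree <- readSpeciesTree(treePath)
  counts <- readCountMatrix(countsPath)
  annotations <- readAnnotations(annotationsPath)
  hdr <- outputHeader(seed, configChecksum(countsPath))
  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile,
                               append = TRUE)
  cat("", file = logFile)
  logLine("DefenseFlux %s analysis started %s",
          as.character(packageVersion("DefenseFlux")),
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logLine("seed: %d", seed)
  t0 <- Sys.time()

  model <- fitBDG(tree, counts, fit)
  if (!model@converged) logLine("WARNING: model fitting did not converge")
  writeModelParameters(model, file.path(outDir, "model_parameters.txt"))

  observed <- rownames(counts)[rowSums(counts) > 0]
  dsFams <- intersect(observed,
                      names(annotations)[annotations != "non-defense"])
  postAll <- posteriorEvents(model, counts)
  allSummary <- summarizeEvents(postAll, label = "all")
  writeEventPosteriors(postAll, file.path(outDir, "event_posteriors.tsv"),
                       header = hdr)
  summaries <- list(all = allSummary)
  relRow <- NULL
  composition <- NULL
  if (length(dsFams) >= 1) {
    postDS <- posteriorEvents(model, counts, families = dsFams)
    dsSummary <- summarizeEvents(postDS, label = "DS")
    summaries$DS <- dsSummary
    ratesAll <- normalizeEvents(allSummary)
    ratesDS <- normalizeEvents(dsSummary)
    relRow <- relativeRates(ratesDS, ratesAll, atgc = atgcId)
    writeRelativeRateTable(relRow, file.path(outDir, "relative_rates.tsv"))
    composition <- tryCatch(compareEventComposition(dsSummary, allSummary),
                            error = function(e) NULL)
  } else {
    logLine("no defense families observed: DS-specific outputs skipped")
    message("no defense families observed: DS-specific outputs skipped")
  }

  coloc <- NULL
  if (!is.null(geneMapPath)) {
    maps <- readGeneMaps(geneMapPath)
    coloc <- list()
    for (lvl in c("gene", "directon")) {
      res <- lapply(maps, function(m) {
        tryCatch(colocalizationTest(m, level = lvl, nReps = nReps,
                                    seed = seed),
                 error = function(e) NULL)
      })
      res <- Filter(Negate(is.null), res)
      if (length(res))
        writeColocalizationResults(res,
          file.path(outDir, sprintf("colocalization_%s.tsv", lvl)),
          header = hdr)
      coloc[[lvl]] <- res
    }
  }
  logLine("finished in %.1f s", as.numeric(difftime(Sys.time(), t0, "secs")))
  invisible(list(model = model, summaries = summaries,
                 rates = if (length(dsFams)) list(DS = ratesDS, all = ratesAll),
                 relativeRates = relRow, composition = composition,
                 colocalization = coloc))
}

#' Summary statistics of a relative-rate table
#'
#' Recomputes the headline statistics of the defense-over-all relative-rate
#' table: per-column means, the number of ATGCs whose gain (and loss) ratio
#' exceeds 1, the quartile flux classification, the extreme rows, and the
#' PCA variance shares.
#'
#' @param table a relative-rate data.frame; defaults to the packaged
#'   36-ATGC table ([loadTable1()])
#' @return a list with `means`, `nGainAbove1`, `nLossAbove1`, `flux`
#'   (class counts), `classification`, `maxRow`, `pca`
#' @examples
#' s <- table1Stats()
#' round(s$means, 2)
#' @export
table1Stats <- function(table = loadTable1()) {
  cls <- classifyFlux(table)
  pca <- pcaRelativeRates(table)
  maxIdx <- which.max(table$all_gde_ratio)
  list(means = meanRatios(table),
       nGainAbove1 = countExceeding(table, "gain_ratio", 1),
       nLossAbove1 = countExceeding(table, "loss_ratio", 1),
       flux = table(cls$flux_class),
       classification = cls,
       maxRow = table[maxIdx, ],
       pca = pca)
}
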