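# Readers and writers for the tabular and tree formats.
# All tabular files are tab-separated UTF-8 with one header line; lines
# starting with '#' are comments. IDs are opaque case-sensitive strings.

#' Read a rooted species tree from a Newick file
#'
#' Branch lengths are mandatory and must be non-negative; leaf labels must be
#' unique. Polytomies are accepted; a bifurcating (or multifurcating) root of
#' the Newick string is taken as the root.
#'
#' @param path path to a Newick file
#' @return a rooted `ape::phylo` tree
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):0.5,C:1.5);", f)
#' tr <- readSpeciesTree(f)
#' @export
readSpeciesTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: empty or malformed file")
  validateSpeciesTree(tree)
  tree
}

#' Validate a species tree
#'
#' @param tree an `ape::phylo`
#' @return the tree, invisibly, after validation
#' @export
validateSpeciesTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (length(tree$tip.label) < 2) stop("a species tree needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf label: ",
    paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("every edge must carry a finite branch length")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  invisible(tree)
}

#' Midpoint rooting
#'
#' Re-roots a tree at the midpoint of its longest leaf-to-leaf path, so that
#' the two deepest leaves are equidistant from the root. Leaf-to-leaf path
#' lengths are preserved.
#'
#' @param tree an `ape::phylo` with finite branch lengths (rooting state
#'   irrelevant)
#' @return a rooted `ape::phylo`
#' @export
midpointRoot <- function(tree) {
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("branch lengths required")
  if (all(tree$edge.length == 0))
    stop("degenerate tree: all branch lengths are zero, midpoint is ambiguous")
  rooted <- phangorn::midpoint(tree)
  validateSpeciesTree(rooted)
  rooted
}

#' Read / write a gene-family count matrix
#'
#' The TSV has a header row of genome IDs, a first column of family IDs and
#' non-negative integer cells. `writeCountMatrix` followed by
#' `readCountMatrix` is the identity.
#'
#' @param path file path
#' @return `readCountMatrix`: an integer matrix with family IDs as rownames
#'   and genome IDs as colnames
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a family column and >= 1 genome column")
  fam <- df[[1]]
  if (anyDuplicated(fam)) stop("duplicate family IDs")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) stop("non-numeric cell in count matrix")
  if (any(num < 0)) stop("negative count")
  if (any(num != floor(num))) stop("non-integer count")
  m <- matrix(as.integer(num), nrow = nrow(df),
              dimnames = list(fam, colnames(df)[-1]))
  m
}

#' @rdname readCountMatrix
#' @param counts integer matrix, families x genomes
#' @export
writeCountMatrix <- function(counts, path) {
  validateCountMatrix(counts)
  df <- data.frame(family = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix, optionally against a tree
#'
#' @param counts integer matrix, families x genomes
#' @param tree optional `ape::phylo`; genome IDs must match the tip labels
#' @return the matrix, invisibly
#' @export
validateCountMatrix <- function(counts, tree = NULL) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry family rownames and genome colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate family IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate genome IDs")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(tree) && !setequal(colnames(counts), tree$tip.label))
    stop("genome IDs must exactly match the tree's leaf labels")
  invisible(counts)
}

#' Read / write a family annotation table
#'
#' Two-column TSV (family_id, class) mapping family IDs to the closed
#' vocabulary {RM, TA, CRISPR-Cas, Abi, other-defense, non-defense}.
#'
#' @param path file path
#' @return `readAnnotations`: a named character vector, family ID -> class
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("annotation table needs columns family_id and class")
  if (anyDuplicated(df[[1]])) stop("duplicate family IDs in annotation")
  bad <- setdiff(unique(df[[2]]), validClasses())
  if (length(bad)) stop("unknown defense class: ", paste(bad, collapse = ", "))
  setNames(df[[2]], df[[1]])
}

#' @rdname readAnnotations
#' @param annotations named character vector, family ID -> class
#' @export
writeAnnotations <- function(annotations, path) {
  bad <- setdiff(unique(annotations), validClasses())
  if (length(bad)) stop("unknown defense class: ", paste(bad, collapse = ", "))
  df <- data.frame(family_id = names(annotations), class = unname(annotations),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-genome chromosome maps
#'
#' The TSV has columns replicon, index, strand, family_id, class, plus one
#' comment line per replicon of the form `# circular: <replicon>=<true|false>`
#' (replicons without such a line are taken as circular).
#'
#' @param path file path
#' @return `readGeneMaps`: a named list of [ChromosomeMap-class], one per
#'   replicon
#' @export
readGeneMaps <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  lines <- readLines(path)
  circ <- list()
  for (l in grep("^#\\s*circular:", lines, value = TRUE)) {
    spec <- sub("^#\\s*circular:\\s*", "", l)
    kv <- strsplit(trimws(spec), "=")[[1]]
    circ[[kv[1]]] <- tolower(trimws(kv[2])) %in% c("true", "1", "yes")
  }
  df <- read.delim(text = lines[!startsWith(lines, "#")],
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("replicon", "index", "strand", "family_id", "class")
  if (!all(need %in% names(df))) stop("gene map needs columns: ",
                                      paste(need, collapse = ", "))
  out <- lapply(split(df, df$replicon), function(d) {
    d <- d[order(as.integer(d$index)), , drop = FALSE]
    if (!identical(as.integer(d$index), seq_len(nrow(d)) - 1L))
      stop("gene indices must be 0..n-1 without gaps on replicon ", d$replicon[1])
    ChromosomeMap(replicon = d$replicon[1], strand = d$strand,
                  family = d$family_id, geneClass = d$class,
                  circular = if (d$replicon[1] %in% names(circ))
                    circ[[d$replicon[1]]] else TRUE)
  })
  out
}

#' @rdname readGeneMaps
#' @param maps list of [ChromosomeMap-class]
#' @export
writeGeneMaps <- function(maps, path) {
  if (is(maps, "ChromosomeMap")) maps <- list(maps)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in maps)
    writeLines(sprintf("# circular: %s=%s", m@replicon,
                       tolower(as.character(m@circular))), con)
  writeLines("replicon\tindex\tstrand\tfamily_id\tclass", con)
  for (m in maps) {
    n <- length(m@strand)
    writeLines(paste(m@replicon, seq_len(n) - 1L, m@strand, m@family,
                     m@geneClass, sep = "\t"), con)
  }
  invisible(path)
}

#' Convert GFF-like gene records to a chromosome map
#'
#' Accepts a minimal GFF-like TSV with columns seqid, start, strand and an
#' attributes column holding `family=<id>` and optionally `class=<class>`
#' key-value pairs (';'-separated). Genes are ordered by start coordinate.
#'
#' @param path file path
#' @param circular logical flag applied to every replicon
#' @return a named list of [ChromosomeMap-class]
#' @export
geneMapFromGff <- function(path, circular = TRUE) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("seqid", "start", "strand", "attributes")
  if (!all(need %in% names(df))) stop("need columns: ", paste(need, collapse = ", "))
  getAttr <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), s))
    vapply(m, function(x) if (length(x) == 2) trimws(x[2]) else NA_character_, "")
  }
  fam <- getAttr(df$attributes, "family")
  if (anyNA(fam)) stop("every record needs a family= attribute")
  cls <- getAttr(df$attributes, "class")
  cls[is.na(cls)] <- "non-defense"
  lapply(split(seq_len(nrow(df)), df$seqid), function(i) {
    i <- i[order(as.numeric(df$start[i]))]
    ChromosomeMap(replicon = df$seqid[i[1]], strand = df$strand[i],
                  family = fam[i], geneClass = cls[i], circular = circular)
  })
}

#' The published defense-versus-all relative-rate table
#'
#' Returns the packaged table of relative genome-dynamics rates in defense
#' systems across 36 groups of closely related prokaryotic genomes (ATGCs):
#' for each event type, the defense-system rate per family divided by the
#' all-gene rate per family, at the published 2-decimal precision.
#'
#' @return a data.frame with columns atgc, genus, gain_ratio, loss_ratio,
#'   expansion_ratio, reduction_ratio, all_gde_ratio (36 rows)
#' @examples
#' t1 <- loadTable1()
#' colMeans(t1[, 3:7])
#' @export
loadTable1 <- function() {
  path <- system.file("extdata", "table1_defense_relative_rates.tsv",
                      package = "DefenseFlux", mustWork = TRUE)
  readRelativeRateTable(path)
}

#' Read / write a relative-rate table
#'
#' @param path file path
#' @return `readRelativeRateTable`: a data.frame with the five ratio columns
#' @export
readRelativeRateTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("atgc", "genus", "gain_ratio", "loss_ratio", "expansion_ratio",
            "reduction_ratio", "all_gde_ratio")
  if (!all(need %in% names(df))) stop("relative-rate table needs columns: ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$atgc)) stop("duplicate ATGC row keys")
  ratios <- as.matrix(df[, need[3:7]])
  if (any(ratios < 0, na.rm = TRUE)) stop("ratios must be non-negative")
  df[, need]
}

#' @rdname readRelativeRateTable
#' @param table a relative-rate data.frame
#' @export
writeRelativeRateTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
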