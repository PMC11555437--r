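## Reading, writing and harmonizing count tables, trees and metadata.

#' Read a sample-by-taxon count table
#'
#' Reads a TSV (header row + id column) or BIOM count table into a
#' validated [CountTable-class].  Orientation of a TSV is declared, never
#' guessed: the default `taxaAreRows = TRUE` matches the common QIIME
#' export; the stored matrix is always samples-in-rows.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (BIOM needs the biomformat package).
#' @param taxaAreRows orientation of the TSV on disk.
#' @return a [CountTable-class].
#' @export
readCountTable <- function(path, format = c("tsv", "biom"),
                           taxaAreRows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))     # taxa x samples
    return(countTable(m, taxaAreRows = TRUE))
  }
  df <- read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                   check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  countTable(m, taxaAreRows = taxaAreRows)
}

#' Write a count table as TSV
#'
#' @param x a [CountTable-class].
#' @param path output path.
#' @param taxaAreRows write taxa-in-rows (default, QIIME-style).
#' @export
writeCountTable <- function(x, path, taxaAreRows = TRUE) {
  m <- countData(x)
  if (taxaAreRows) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (taxaAreRows) "taxon" else "sample"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a rooted phylogenetic tree
#'
#' Reads Newick via \pkg{ape} and enforces what the phylogenetic kernels
#' need: every branch length present and nonnegative, unique non-empty
#' leaf labels, rooted topology.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] object.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick: ", path)
  validateTree(tr)
}

#' @describeIn readTree validate an in-memory `phylo` object.
#' @param tree an [ape::phylo] object.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("unlabeled leaf")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf label")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Read sample metadata from TSV
#'
#' First column is the sample id; named columns supply the response,
#' treatment and covariates.  Missing values are a hard error.
#'
#' @param path TSV path (header row, sample ids in first column).
#' @param responseCol,treatmentCol column names for response/treatment.
#' @param covariateCols character vector of covariate column names
#'   (may be empty).
#' @param family `"gaussian"` or `"binomial"`.
#' @return a [SampleMetadata-class].
#' @export
readSampleMetadata <- function(path, responseCol, treatmentCol,
                               covariateCols = character(),
                               family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                   check.names = FALSE)
  need <- c(responseCol, treatmentCol, covariateCols)
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata column not found: ",
                         paste(miss, collapse = ", "))
  Z <- if (length(covariateCols))
    as.matrix(df[, covariateCols, drop = FALSE]) else NULL
  sampleMetadata(response = df[[responseCol]],
                 treatment = df[[treatmentCol]],
                 covariates = Z, family = family,
                 sampleIDs = rownames(df))
}

#' Harmonize count table, tree and metadata to a shared sample set
#'
#' Restricts the count table and metadata to their common samples in the
#' order of the count table (the canonical order), and prunes the tree to
#' the table's taxa.  A table taxon absent from the tree is an error, not
#' a silent drop.
#'
#' @param table a [CountTable-class].
#' @param tree an [ape::phylo] or `NULL`.
#' @param meta a [SampleMetadata-class].
#' @return `list(table =, tree =, meta =)`, all row-aligned.
#' @export
harmonize <- function(table, tree = NULL, meta) {
  stopifnot(is(table, "CountTable"), is(meta, "SampleMetadata"))
  common <- intersect(sampleIDs(table), meta@sampleIDs)
  if (length(common) == 0) stop("empty sample intersection")
  keep <- sampleIDs(table)[sampleIDs(table) %in% common]
  tab <- countTable(countData(table)[keep, , drop = FALSE])
  idx <- match(keep, meta@sampleIDs)
  met <- sampleMetadata(response = meta@response[idx],
                        treatment = meta@treatment[idx],
                        covariates = if (ncol(meta@covariates))
                          meta@covariates[idx, , drop = FALSE] else NULL,
                        family = meta@family, sampleIDs = keep)
  if (!is.null(tree)) {
    tree <- validateTree(tree)
    missing <- setdiff(taxonIDs(tab), tree$tip.label)
    if (length(missing))
      stop("taxon not found in tree: ", paste(missing, collapse = ", "))
    if (length(setdiff(tree$tip.label, taxonIDs(tab))))
      tree <- ape::keep.tip(tree, taxonIDs(tab))
  }
  list(table = tab, tree = tree, meta = met)
}
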