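#' Read a sample-by-taxon abundance table from a delimited file
#'
#' Reads a TSV (or other delimiter) with one header row and row names in
#' the first column, validates it, and returns a counts-mode
#' \linkS4class{AbundanceTable} oriented samples x taxa regardless of the
#' file's orientation.
#'
#' @param path path to the delimited file.
#' @param orientation "samples_rows" (default) if file rows are samples,
#'   "taxa_rows" if file rows are taxa (the table is transposed on read).
#' @param sep field delimiter, default tab.
#' @return A counts-mode \linkS4class{AbundanceTable}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(matrix(1:6, 3, 2, dimnames = list(paste0("s", 1:3),
#'             c("t1", "t2"))), f, sep = "\t", quote = FALSE)
#' readAbundanceTable(f)
#' @export
readAbundanceTable <- function(path,
                               orientation = c("samples_rows", "taxa_rows"),
                               sep = "\t") {
  orientation <- match.arg(orientation)
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    badRow <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))))[1]
    stop(sprintf("non-numeric value in column '%s', row '%s'",
                 names(df)[bad], rownames(df)[badRow]), call. = FALSE)
  }
  if (orientation == "taxa_rows") m <- t(m)
  AbundanceTable(m, mode = "counts")
}

#' Read a sample metadata table
#'
#' Expects a delimited file with columns sample_id, habitat, site, plot and
#' optionally pH and elevation. Habitat labels are validated against the
#' three strata of the system (litter, sphagnum, soil).
#'
#' @param path path to the TSV file.
#' @param sep field delimiter.
#' @return A data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path, sep = "\t") {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  meta <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
  need <- c("sample_id", "habitat", "site", "plot")
  miss <- setdiff(need, names(meta))
  stopIfNot(length(miss) == 0,
            paste0("metadata lacks columns: ", paste(miss, collapse = ", ")))
  stopIfNot(!anyDuplicated(meta$sample_id), "duplicated sample_id")
  bad <- setdiff(unique(meta$habitat), HABITATS)
  stopIfNot(length(bad) == 0,
            paste0("unknown habitat labels: ", paste(bad, collapse = ", ")))
  if ("pH" %in% names(meta))
    stopIfNot(all(meta$pH > 0 & meta$pH < 14), "pH must lie in (0, 14)")
  meta
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Thin wrapper over \code{ape::read.tree} that enforces the invariants the
#' phylogenetic metrics need: rooted topology, unique tip labels,
#' non-negative branch lengths.
#'
#' @param path path to a Newick file.
#' @return An \code{ape::phylo} object.
#' @export
readTree <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  tree <- ape::read.tree(path)
  stopIfNot(inherits(tree, "phylo"), "could not parse a tree from file")
  stopIfNot(ape::is.rooted(tree), "tree must be rooted")
  stopIfNot(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  stopIfNot(!is.null(tree$edge.length) && all(tree$edge.length >= 0),
            "tree must have non-negative branch lengths")
  tree
}

#' Write an AbundanceTable to TSV
#'
#' @param tab an \linkS4class{AbundanceTable}.
#' @param path output path; samples are written as rows.
#' @return Invisibly, \code{path}.
#' @export
writeAbundanceTable <- function(tab, path) {
  stopIfNot(is(tab, "AbundanceTable"), "input must be an AbundanceTable")
  df <- data.frame(sample_id = sampleIDs(tab), abundances(tab),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
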