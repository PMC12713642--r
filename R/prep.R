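#' Remove rare ASVs
#'
#' Drops every taxon whose total count across all samples is below
#' \code{minReads}. With the default of 10 this subsumes the removal of
#' singletons and doubletons. The filter is defined on dataset-wide totals,
#' so it is idempotent and the sample set is never changed.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param minReads minimum total count a taxon must reach to be kept.
#' @return The filtered counts-mode table.
#' @examples
#' tab <- AbundanceTable(matrix(c(1, 0, 4, 6), 2, 2))
#' nTaxa(filterRareASVs(tab))  # the 1-read taxon is removed
#' @export
filterRareASVs <- function(tab, minReads = 10) {
  assertCounts(tab, "filterRareASVs")
  if (nTaxa(tab) == 0) return(tab)
  keep <- colSums(abundances(tab)) >= minReads
  tab[, keep]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth}, as a single seeded draw. The same seed always yields a
#' bit-identical table.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable} with integer counts.
#' @param depth target reads per sample; every sample total must be at
#'   least \code{depth}.
#' @param seed integer seed for the draw.
#' @return A counts-mode table whose row sums all equal \code{depth}.
#' @export
rarefy <- function(tab, depth, seed) {
  assertCounts(tab, "rarefy")
  stopIfNot(length(depth) == 1 && depth >= 1 && depth == round(depth),
            "depth must be a positive integer")
  v <- abundances(tab)
  tot <- rowSums(v)
  low <- tot < depth
  if (any(low))
    stop(sprintf("samples with fewer than %d reads: %s", as.integer(depth),
                 paste(head(rownames(v)[low], 10), collapse = ", ")),
         call. = FALSE)
  out <- withSeed(seed, {
    t(apply(v, 1, function(cnt) {
      if (sum(cnt) == depth) return(cnt)
      drawn <- sample(rep.int(seq_along(cnt), cnt), depth)
      tabulate(drawn, nbins = length(cnt))
    }))
  })
  dimnames(out) <- dimnames(v)
  AbundanceTable(out, mode = "counts")
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total. All-zero samples stay all-zero
#' and are reported in a warning.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @return A relative-mode table.
#' @export
toRelative <- function(tab) {
  assertCounts(tab, "toRelative")
  v <- abundances(tab)
  tot <- rowSums(v)
  if (any(tot == 0) && nrow(v))
    warning(sprintf("all-zero samples left as zero: %s",
                    paste(head(rownames(v)[tot == 0], 10), collapse = ", ")))
  tot[tot == 0] <- 1
  AbundanceTable(v / tot, mode = "relative")
}

#' Full preprocessing step
#'
#' Applies the rare-taxon filter, then rarefies to \code{depth}
#' (\code{"auto"} = minimum sample total after filtering), reporting what
#' was removed.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param minReads rare-taxon threshold (total reads), default 10.
#' @param depth rarefaction depth or "auto".
#' @param seed integer seed for the rarefaction draw.
#' @param exclude optional character vector of taxon ids to drop before
#'   filtering (e.g. externally identified contaminants).
#' @return A list with \code{counts} (rarefied table), \code{depth} and
#'   \code{removed} (taxa removed by the rare filter).
#' @export
prepCounts <- function(tab, minReads = 10, depth = "auto", seed = 1,
                       exclude = NULL) {
  assertCounts(tab, "prepCounts")
  if (length(exclude))
    tab <- tab[, setdiff(taxonIDs(tab), exclude)]
  before <- taxonIDs(tab)
  filt <- filterRareASVs(tab, minReads = minReads)
  if (identical(depth, "auto")) depth <- min(rowSums(abundances(filt)))
  rar <- rarefy(filt, depth = depth, seed = seed)
  list(counts = rar, depth = as.integer(depth),
       removed = setdiff(before, taxonIDs(filt)))
}
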