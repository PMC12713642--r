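#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn AbundanceTable-class abundance matrix (samples x taxa)
#' @param x an AbundanceTable.
#' @param ... unused.
#' @export
setMethod("abundances", "AbundanceTable", function(x, ...) x@values)

#' @describeIn AbundanceTable-class sample identifiers
#' @export
setMethod("sampleIDs", "AbundanceTable", function(x) rownames(x@values))

#' @describeIn AbundanceTable-class taxon identifiers
#' @export
setMethod("taxonIDs", "AbundanceTable", function(x) colnames(x@values))

#' @describeIn AbundanceTable-class "counts" or "relative"
#' @export
setMethod("abundanceMode", "AbundanceTable", function(x) x@mode)

#' @describeIn AbundanceTable-class number of samples
#' @export
setMethod("nSamples", "AbundanceTable", function(x) nrow(x@values))

#' @describeIn AbundanceTable-class number of taxa
#' @export
setMethod("nTaxa", "AbundanceTable", function(x) ncol(x@values))

#' Subset an AbundanceTable
#'
#' \code{x[i, j]} keeps samples \code{i} and taxa \code{j}. Subsetting a
#' relative-mode table does not renormalise rows, so the result is
#' downgraded to an unvalidated matrix unless rows still close to 1; to
#' stay in relative mode re-run \code{\link{toRelative}} on counts.
#'
#' @param x AbundanceTable.
#' @param i,j sample / taxon indices (any standard matrix index).
#' @param drop ignored (always FALSE).
#' @return An AbundanceTable in counts mode, or in relative mode when row
#'   sums are preserved.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v <- v[i, j, drop = FALSE]
  mode <- x@mode
  if (mode == "relative") {
    rs <- rowSums(v)
    if (any(rs > 0 & abs(rs - 1) > 1e-9)) mode <- "counts"
  }
  new("AbundanceTable", values = v, mode = mode)
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d samples x %d taxa (%s mode)\n",
              nrow(object@values), ncol(object@values), object@mode))
  if (nrow(object@values) && object@mode == "counts")
    cat(sprintf("  sample totals: %s .. %s reads\n",
                format(min(rowSums(object@values))),
                format(max(rowSums(object@values)))))
  invisible(object)
})

setMethod("show", "NCMFit", function(object) {
  tab <- table(factor(object@taxa$partition,
                      levels = c("above", "within", "below")))
  cat(sprintf("Sloan neutral community model fit\n  m = %.5g  Nm = %.5g  R2 = %.4f\n",
              object@m, object@m * object@N, object@r2))
  cat(sprintf("  N = %s reads, detection limit d = %.3g\n",
              format(object@N), object@d))
  cat(sprintf("  partition (%.0f%% envelope): above %d / within %d / below %d\n",
              100 * object@ciLevel, tab["above"], tab["within"], tab["below"]))
  invisible(object)
})

#' @describeIn CoreClassification-class per-taxon SU/ES/EC labels
#' @param x a CoreClassification.
#' @export
setMethod("taxonLabels", "CoreClassification",
          function(x) setNames(x@taxa$label, x@taxa$taxon))

setMethod("show", "CoreClassification", function(object) {
  tab <- table(factor(object@taxa$label,
                      levels = c("SU", "ES", "EC", "core-unresolved",
                                 "non-core")))
  cat(sprintf("Core classification (host = %s, minRA = %g, minPrev = %g)\n",
              object@host, object@minRA, object@minPrev))
  cat(sprintf("  core: %d of %d taxa | SU %d, ES %d, EC %d, unresolved %d\n",
              sum(object@taxa$is_core), nrow(object@taxa),
              tab["SU"], tab["ES"], tab["EC"], tab["core-unresolved"]))
  invisible(object)
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (|rho| >= %g, p <= %g)\n",
              igraph::vcount(object@graph), nrow(object@edges),
              object@rThreshold, object@pThreshold))
  if (nrow(object@edges))
    cat(sprintf("  %d positive / %d negative edges\n",
                sum(object@edges$sign > 0), sum(object@edges$sign < 0)))
  invisible(object)
})

setMethod("show", "PathFit", function(object) {
  cat(sprintf("Piecewise path model: %d edges, %d independence claims\n",
              nrow(object@coefficients), nrow(object@claims)))
  cat(sprintf("  Fisher's C = %.3f, df = %d, p = %.4f -> %s\n",
              object@fisherC, as.integer(object@df), object@p,
              if (evaluateFit(object)) "accept" else "reject"))
  invisible(object)
})
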