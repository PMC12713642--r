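#' Build a thresholded co-occurrence network
#'
#' Keeps an undirected edge between two taxa iff |rho| is at least
#' \code{rThreshold} (inclusive) and the correlation-test p-value (t
#' approximation with \code{nSamples} observations) is at most
#' \code{pThreshold}. NA correlations (constant taxa) never form edges.
#'
#' @param corr symmetric correlation matrix with taxon dimnames (e.g.
#'   from \code{\link{spearmanMatrix}}).
#' @param rThreshold absolute-correlation threshold in (0, 1),
#'   default 0.6.
#' @param pThreshold p-value threshold, default 0.05.
#' @param nSamples number of samples the correlations were computed from
#'   (>= 4).
#' @param adjust "none" (default; edge count is threshold-driven) or
#'   "BH" for Benjamini-Hochberg adjustment of the edge p-values.
#' @return A \linkS4class{CooccurrenceNetwork}.
#' @export
buildNetwork <- function(corr, rThreshold = 0.6, pThreshold = 0.05,
                         nSamples, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopIfNot(rThreshold > 0 && rThreshold < 1,
            "rThreshold must lie in (0, 1)")
  stopIfNot(nSamples >= 4, "need at least 4 samples")
  taxa <- rownames(corr)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  rho <- corr[ut]
  dfree <- nSamples - 2
  tstat <- rho * sqrt(dfree / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(abs(tstat), dfree, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  if (adjust == "BH") p <- p.adjust(p, "BH")
  keep <- !is.na(rho) & abs(rho) >= rThreshold & p <= pThreshold
  edges <- data.frame(taxon_a = taxa[ut[keep, 1]],
                      taxon_b = taxa[ut[keep, 2]],
                      rho = rho[keep], p = p[keep],
                      sign = sign(rho[keep]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("taxon_a", "taxon_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = taxa))
  new("CooccurrenceNetwork", graph = g, edges = edges,
      rThreshold = rThreshold, pThreshold = pThreshold)
}

#' Network robustness under random node removal
#'
#' For each of \code{nOrders} seeded uniform-random removal orders, nodes
#' are removed cumulatively at each fraction of a grid over [0, 1] and
#' the size of the largest connected component, as a fraction of the
#' initial node count, is recorded. Robustness is the trapezoidal area
#' under the order-averaged curve; a complete graph scores ~0.5 (pure
#' removal loss), fragile topologies score less.
#'
#' @param net \linkS4class{CooccurrenceNetwork} or an igraph object with
#'   >= 2 nodes.
#' @param nOrders number of random removal orders (default 100).
#' @param gridStep removal-fraction grid step (default 0.05).
#' @param seed integer seed.
#' @return A list with \code{fractions}, \code{lcc} (mean largest
#'   component fraction at each grid point) and \code{robustness}
#'   (AUC in [0, 1]).
#' @export
networkRobustness <- function(net, nOrders = 100, gridStep = 0.05,
                              seed = 1) {
  g <- if (is(net, "CooccurrenceNetwork")) net@graph else net
  n <- igraph::vcount(g)
  if (n == 0) {
    warning("empty network: robustness is 0")
    return(list(fractions = c(0, 1), lcc = c(0, 0), robustness = 0))
  }
  stopIfNot(n >= 2, "need at least 2 nodes")
  fr <- seq(0, 1, by = gridStep)
  if (fr[length(fr)] < 1) fr <- c(fr, 1)
  curves <- withSeed(seed, {
    vapply(seq_len(nOrders), function(o) {
      ord <- sample.int(n)
      vapply(fr, function(f) {
        k <- floor(f * n)
        if (k >= n) return(0)
        sub <- igraph::delete_vertices(g, ord[seq_len(k)])
        max(igraph::components(sub)$csize) / n
      }, numeric(1))
    }, numeric(length(fr)))
  })
  lcc <- rowMeans(curves)
  auc <- sum(diff(fr) * (head(lcc, -1) + lcc[-1]) / 2)
  list(fractions = fr, lcc = lcc, robustness = auc)
}

#' Export a network as an edge-list TSV
#'
#' @param net \linkS4class{CooccurrenceNetwork}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path) {
  header <- sprintf("# co-occurrence network: |rho| >= %g, p <= %g",
                    net@rThreshold, net@pThreshold)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(net@edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
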