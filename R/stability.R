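#' Average variation degree (AVD)
#'
#' Per-sample compositional-variability score: for each taxon the mean
#' and standard deviation across the sample set are computed; a sample's
#' AVD is the mean absolute z-score of its abundances over the taxa with
#' non-zero variation. Low AVD means the sample sits close to the group's
#' mean profile (convergent, stable composition).
#'
#' @param tab relative-mode \linkS4class{AbundanceTable}, or any numeric
#'   matrix (samples x variables) for calibration use.
#' @param sampleSet optional sample ids restricting the set the
#'   reference mean/sd and the scores are computed over (default: all).
#' @return data.frame: sample_id, avd.
#' @export
avd <- function(tab, sampleSet = NULL) {
  if (is(tab, "AbundanceTable")) {
    assertRelative(tab, "avd")
    v <- abundances(tab)
  } else {
    v <- as.matrix(tab)
    if (is.null(rownames(v))) rownames(v) <- paste0("sample_", seq_len(nrow(v)))
  }
  if (!is.null(sampleSet)) {
    miss <- setdiff(sampleSet, rownames(v))
    stopIfNot(length(miss) == 0,
              paste0("unknown samples: ", paste(head(miss, 5), collapse = ", ")))
    v <- v[sampleSet, , drop = FALSE]
  }
  stopIfNot(nrow(v) >= 3, "AVD needs at least 3 samples")
  mu <- colMeans(v)
  sig <- apply(v, 2, sd)
  keep <- sig > 0
  stopIfNot(any(keep), "all taxa are constant: no variation to measure")
  z <- abs(sweep(sweep(v[, keep, drop = FALSE], 2, mu[keep]), 2, sig[keep],
                 "/"))
  data.frame(sample_id = rownames(v), avd = rowMeans(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regress a stability metric on core-group abundance
#'
#' Ordinary least squares of y (a per-sample stability metric) on x
#' (per-sample relative abundance of a core group). Pairs with undefined
#' (NA) y are dropped and counted.
#'
#' @param x per-sample group relative abundance.
#' @param y per-sample stability metric; NA values are excluded.
#' @return data.frame: slope, intercept, r2, p (F-test), n_used,
#'   n_dropped.
#' @export
stabilityRegression <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  nDropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  stopIfNot(length(x) >= 5, "need at least 5 paired finite observations")
  stopIfNot(var(x) > 0, "x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  pF <- if (var(y) == 0) 1 else
    pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
       lower.tail = FALSE)
  data.frame(slope = coef(fit)[["x"]], intercept = coef(fit)[["(Intercept)"]],
             r2 = sm$r.squared, p = as.numeric(pF),
             n_used = length(x), n_dropped = nDropped)
}

#' Bootstrap replicates of network robustness
#'
#' Rebuilds the co-occurrence network on bootstrap resamples of the
#' samples and records its robustness, providing a distribution of the
#' community-level robustness statistic that can be paired with
#' per-replicate group abundances in regressions.
#'
#' @param tab relative-mode \linkS4class{AbundanceTable}.
#' @param nBoot number of bootstrap replicates (default 30).
#' @param rThreshold,pThreshold network thresholds.
#' @param nOrders,gridStep robustness settings (see
#'   \code{\link{networkRobustness}}).
#' @param seed integer seed.
#' @return data.frame: replicate, robustness, n_edges, plus the mean
#'   group x abundance over the resampled samples in attribute
#'   "samples" (list of index vectors).
#' @export
robustnessReplicates <- function(tab, nBoot = 30, rThreshold = 0.6,
                                 pThreshold = 0.05, nOrders = 50,
                                 gridStep = 0.1, seed = 1) {
  assertRelative(tab, "robustnessReplicates")
  n <- nSamples(tab)
  idxList <- withSeed(seed, lapply(seq_len(nBoot), function(b)
    sample.int(n, n, replace = TRUE)))
  out <- do.call(rbind, lapply(seq_len(nBoot), function(b) {
    m <- abundances(tab)[idxList[[b]], , drop = FALSE]
    rownames(m) <- paste0("r", seq_len(nrow(m)))
    sub <- AbundanceTable(m, mode = "relative")
    corr <- spearmanMatrix(sub)
    net <- buildNetwork(corr, rThreshold = rThreshold,
                        pThreshold = pThreshold, nSamples = n)
    if (igraph::vcount(net@graph) < 2 || nrow(net@edges) == 0)
      return(data.frame(replicate = b, robustness = 0, n_edges = 0))
    rb <- networkRobustness(net, nOrders = nOrders, gridStep = gridStep,
                            seed = stageSeed(seed, paste0("boot", b)))
    data.frame(replicate = b, robustness = rb$robustness,
               n_edges = nrow(net@edges))
  }))
  attr(out, "samples") <- idxList
  out
}
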