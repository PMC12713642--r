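#' Per-taxon occurrence statistics for the neutral model
#'
#' For each taxon: mean within-sample relative abundance \code{p} and
#' occurrence frequency \code{freq} (fraction of samples with count > 0).
#' Taxa absent from every sample are dropped.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable} with >= 2 samples.
#' @return data.frame: taxon, p, freq.
#' @export
occurrenceStats <- function(tab) {
  assertCounts(tab, "occurrenceStats")
  stopIfNot(nSamples(tab) >= 2, "need at least 2 samples")
  v <- abundances(tab)
  rel <- v / pmax(rowSums(v), 1)
  p <- colMeans(rel)
  f <- colMeans(v > 0)
  keep <- p > 0
  data.frame(taxon = colnames(v)[keep], p = p[keep], freq = f[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted occurrence frequency under Sloan's neutral model
#'
#' The stationary relative abundance of a taxon with metacommunity mean
#' abundance \code{p} follows a Beta(N m p, N m (1 - p)) distribution;
#' the predicted occurrence frequency is the probability mass above the
#' detection limit \code{d}: \code{1 - pbeta(d, N m p, N m (1 - p))}.
#'
#' @param p mean relative abundance(s), in (0, 1).
#' @param m migration probability (> 0).
#' @param N community size (reads per sample).
#' @param d detection limit as a relative abundance.
#' @return Predicted occurrence frequency in [0, 1] (vectorised over p).
#' @export
predictFreq <- function(p, m, N, d) {
  stopIfNot(m > 0, "migration rate m must be positive")
  pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

## sum of squared residuals of the NCM at migration rate m
.ncmSSE <- function(m, stats, N, d)
  sum((stats$freq - predictFreq(stats$p, m, N, d))^2)

#' Fit Sloan's neutral community model
#'
#' Least-squares fit of the migration rate m: minimises the sum of
#' squared differences between observed occurrence frequencies and
#' \code{\link{predictFreq}} over a bounded search m in (1e-6, 1]
#' (log-spaced grid scan refined by golden-section search). The fit
#' statistic is \code{r2 = 1 - SSE/SST}; it may be negative for
#' pathological fits and is never clipped. Taxa are then partitioned
#' against a Wilson confidence envelope around the fitted curve.
#'
#' @param stats data.frame from \code{\link{occurrenceStats}} (>= 10
#'   taxa), or a counts-mode \linkS4class{AbundanceTable}.
#' @param N community size (reads per sample); for a rarefied table this
#'   is the rarefaction depth.
#' @param d detection limit (relative abundance). Default NULL = half
#'   the smallest nonzero within-sample relative abundance when a table
#'   is supplied (a taxon is recorded absent when its count is 0, i.e.
#'   its underlying frequency lies below half a count — the midpoint
#'   continuity correction removes the discretisation bias in m), else
#'   0.5/N.
#' @param nSamplesObs number of samples behind the frequencies (needed for
#'   the Wilson envelope; inferred when an AbundanceTable is supplied).
#' @param ciLevel envelope confidence level, default 0.95.
#' @return An \linkS4class{NCMFit}.
#' @examples
#' p <- exp(seq(log(1e-4), log(0.05), length.out = 40))
#' stats <- data.frame(taxon = paste0("t", seq_along(p)), p = p,
#'                     freq = predictFreq(p, m = 0.2, N = 1000, d = 1e-3))
#' fitNCM(stats, N = 1000, d = 1e-3, nSamplesObs = 50)
#' @export
fitNCM <- function(stats, N, d = NULL, nSamplesObs = NULL, ciLevel = 0.95) {
  if (is(stats, "AbundanceTable")) {
    nSamplesObs <- nSamples(stats)
    if (is.null(d)) {
      v <- abundances(stats)
      rel <- v / pmax(rowSums(v), 1)
      d <- min(rel[rel > 0]) / 2
    }
    stats <- occurrenceStats(stats)
  }
  stopIfNot(nrow(stats) >= 10, "need at least 10 taxa to fit the NCM")
  stopIfNot(!is.null(nSamplesObs),
            "nSamplesObs is required when passing a stats frame")
  if (is.null(d)) d <- 0.5 / N
  lo <- 1e-6
  grid <- exp(seq(log(lo), log(1), length.out = 200))
  sse <- vapply(grid, .ncmSSE, numeric(1), stats = stats, N = N, d = d)
  if (all(!is.finite(sse)))
    stop("NCM fit failed: objective not finite anywhere on (1e-6, 1]",
         call. = FALSE)
  i <- which.min(sse)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  ## refine on the log scale for resolution at small m
  optLog <- optimize(function(lm) .ncmSSE(exp(lm), stats, N, d),
                     interval = log(c(max(lo, bracket[1] / 2),
                                      min(1, bracket[2] * 2))),
                     tol = 1e-12)
  m <- exp(optLog$minimum)
  sseBest <- optLog$objective
  sst <- sum((stats$freq - mean(stats$freq))^2)
  r2 <- 1 - sseBest / sst
  fit <- new("NCMFit", m = m, N = as.numeric(N), d = d, r2 = r2,
             ciLevel = ciLevel,
             taxa = cbind(stats, pred = predictFreq(stats$p, m, N, d),
                          lower = 0, upper = 1,
                          partition = "within",
                          stringsAsFactors = FALSE))
  partitionTaxa(fit, nSamplesObs = nSamplesObs, ciLevel = ciLevel)
}

## Wilson score interval for a proportion
.wilson <- function(phat, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

#' Partition taxa against the neutral envelope
#'
#' Builds a Wilson binomial interval at \code{ciLevel} around each
#' taxon's predicted occurrence frequency (with n = number of samples)
#' and labels the taxon "above" or "below" when its observed frequency
#' falls outside the band, else "within".
#'
#' @param fit an \linkS4class{NCMFit}.
#' @param nSamplesObs number of samples behind the observed frequencies.
#' @param ciLevel confidence level, default the fit's.
#' @param exact use exact binomial (Clopper-Pearson) bounds instead of
#'   Wilson.
#' @return The fit with its taxa partition updated.
#' @export
partitionTaxa <- function(fit, nSamplesObs, ciLevel = fit@ciLevel,
                          exact = FALSE) {
  tx <- fit@taxa
  if (exact) {
    a <- (1 - ciLevel) / 2
    k <- tx$pred * nSamplesObs
    band <- cbind(lower = qbeta(a, k, nSamplesObs - k + 1),
                  upper = qbeta(1 - a, k + 1, nSamplesObs - k))
    band[tx$pred == 0, "lower"] <- 0
    band[tx$pred == 1, "upper"] <- 1
  } else {
    band <- .wilson(tx$pred, nSamplesObs, ciLevel)
  }
  tx$lower <- band[, "lower"]
  tx$upper <- band[, "upper"]
  tx$partition <- ifelse(tx$freq > tx$upper, "above",
                         ifelse(tx$freq < tx$lower, "below", "within"))
  initialize(fit, taxa = tx, ciLevel = ciLevel)
}

#' Summary of an NCM fit and its partition fractions
#'
#' @param fit an \linkS4class{NCMFit}.
#' @return One-row data.frame: m, Nm, r2, d, N, n_taxa and the fractions
#'   of taxa above / within / below the envelope (summing to 1).
#' @export
ncmSummary <- function(fit) {
  tab <- table(factor(fit@taxa$partition,
                      levels = c("above", "within", "below")))
  n <- nrow(fit@taxa)
  data.frame(m = fit@m, Nm = fit@m * fit@N, r2 = fit@r2, d = fit@d,
             N = fit@N, n_taxa = n,
             frac_above = as.numeric(tab["above"]) / n,
             frac_within = as.numeric(tab["within"]) / n,
             frac_below = as.numeric(tab["below"]) / n)
}
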