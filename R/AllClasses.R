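#' phyllocore: stratified core microbiomes and community stability
#'
#' Analysis of vertically stratified host-environment microbiome systems
#' (e.g. a litter-moss-soil profile): neutral vs deterministic assembly,
#' stratification of the host core microbiome into host-specific and
#' environmental components, and the contribution of each component to
#' community stability and path-model structure.
#'
#' @section Main entry points:
#' \itemize{
#'   \item \code{\link{simulateStratifiedSystem}} — synthetic fixtures with
#'     ground truth.
#'   \item \code{\link{filterRareASVs}}, \code{\link{rarefy}},
#'     \code{\link{toRelative}} — preprocessing.
#'   \item \code{\link{fitNCM}} — Sloan neutral community model.
#'   \item \code{\link{detectCore}}, \code{\link{classifyCore}} — core
#'     detection and SU/ES/EC stratification.
#'   \item \code{\link{connectedness}}, \code{\link{cohesion}},
#'     \code{\link{buildNetwork}}, \code{\link{networkRobustness}} —
#'     cohesion and co-occurrence networks.
#'   \item \code{\link{brayCurtis}}, \code{\link{nmds}},
#'     \code{\link{permanova}}, \code{\link{mantelTest}} — community
#'     structure.
#'   \item \code{\link{avd}}, \code{\link{stabilityRegression}} — stability.
#'   \item \code{\link{fitPaths}}, \code{\link{evaluateFit}} — piecewise
#'     path models.
#'   \item \code{\link{runPipeline}} — full orchestration with a manifest.
#' }
#'
#' @name phyllocore-package
#' @aliases phyllocore
#' @import methods
#' @importFrom stats cor sd var lm pf pt pchisq pbeta qbeta qnorm pnorm
#'   rnorm runif rlnorm rpois rbinom optimize coef vcov anova as.dist
#'   dist isoreg cmdscale setNames quantile plogis qlogis p.adjust
#'   as.formula complete.cases rexp aggregate terms model.matrix ptukey
#'   resid relevel predict logLik cov2cor delete.response
#' @importFrom utils read.table write.table head packageVersion combn
"_PACKAGE"

#' AbundanceTable: samples x taxa abundance matrix
#'
#' The universal exchange object of the package: a non-negative numeric
#' matrix with samples as rows and taxa as columns, tagged with a
#' \code{mode} flag ("counts" or "relative"). In relative mode every
#' non-empty row sums to 1 (tolerance 1e-9).
#'
#' @slot values numeric matrix, samples x taxa, with unique dimnames.
#' @slot mode character, "counts" or "relative".
#' @seealso \code{\link{AbundanceTable}} (constructor),
#'   \code{\link{abundances}}, \code{\link{toRelative}}
#' @export
setClass("AbundanceTable",
  representation(values = "matrix", mode = "character"))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if ((nrow(v) && is.null(rownames(v))) ||
      (ncol(v) && is.null(colnames(v))))
    msgs <- c(msgs, "values must carry sample (row) and taxon (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate sample identifiers")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate taxon identifiers")
  }
  if (length(v) && any(v < 0, na.rm = TRUE))
    msgs <- c(msgs, "negative abundances are not allowed")
  if (anyNA(v)) msgs <- c(msgs, "missing abundances are not allowed")
  if (!(length(object@mode) == 1L && object@mode %in% c("counts", "relative")))
    msgs <- c(msgs, "mode must be 'counts' or 'relative'")
  else if (object@mode == "relative" && nrow(v) && ncol(v)) {
    rs <- rowSums(v)
    bad <- rs > 0 & abs(rs - 1) > 1e-9
    if (any(bad))
      msgs <- c(msgs, paste0("relative-mode rows must sum to 1 (off: ",
                             paste(head(rownames(v)[bad], 5), collapse = ", "),
                             ")"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix (samples x taxa). If dimnames are missing
#'   they are filled in as \code{sample_i} / \code{taxon_j}.
#' @param mode "counts" (default) or "relative".
#' @return An \linkS4class{AbundanceTable}.
#' @examples
#' m <- matrix(c(5, 0, 2, 3, 1, 0), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("t1", "t2")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values))
    colnames(values) <- paste0("taxon_", seq_len(ncol(values)))
  new("AbundanceTable", values = values, mode = mode)
}

#' NCMFit: fitted Sloan neutral community model
#'
#' @slot m migration probability in (0, 1].
#' @slot N community size (reads per sample) used in the fit.
#' @slot d detection limit as a relative abundance.
#' @slot r2 fit statistic 1 - SSE/SST (may be negative; never clipped).
#' @slot ciLevel confidence level of the partition envelope.
#' @slot taxa data.frame with columns taxon, p (mean relative abundance),
#'   freq (occurrence frequency), pred (predicted frequency), lower, upper
#'   (envelope) and partition in {above, within, below}.
#' @export
setClass("NCMFit",
  representation(m = "numeric", N = "numeric", d = "numeric", r2 = "numeric",
                 ciLevel = "numeric", taxa = "data.frame"))

setValidity("NCMFit", function(object) {
  msgs <- character()
  if (!(object@m > 0 && object@m <= 1)) msgs <- c(msgs, "m must lie in (0, 1]")
  if (object@N <= 0) msgs <- c(msgs, "N must be positive")
  if (!(object@ciLevel > 0 && object@ciLevel < 1))
    msgs <- c(msgs, "ciLevel must lie in (0, 1)")
  need <- c("taxon", "p", "freq", "pred", "partition")
  if (!all(need %in% names(object@taxa)))
    msgs <- c(msgs, "taxa frame must have taxon/p/freq/pred/partition")
  else if (!all(object@taxa$partition %in% c("above", "within", "below")))
    msgs <- c(msgs, "partition labels must be above/within/below")
  if (length(msgs)) msgs else TRUE
})

#' CoreClassification: SU / ES / EC stratification of the host core
#'
#' @slot host the host habitat label.
#' @slot minRA,minPrev core-detection thresholds (inclusive).
#' @slot alpha significance level of the enrichment contrasts.
#' @slot taxa data.frame with one row per taxon: is_core, label in
#'   {SU, ES, EC, core-unresolved, non-core}, host prevalence, mean host
#'   relative abundance, adjusted contrast p-values vs each non-host
#'   habitat.
#' @export
setClass("CoreClassification",
  representation(host = "character", minRA = "numeric", minPrev = "numeric",
                 alpha = "numeric", taxa = "data.frame"))

setValidity("CoreClassification", function(object) {
  msgs <- character()
  ok <- c("SU", "ES", "EC", "core-unresolved", "non-core")
  if (!all(object@taxa$label %in% ok))
    msgs <- c(msgs, "unknown core labels")
  if (any(object@taxa$is_core & object@taxa$label == "non-core"))
    msgs <- c(msgs, "core taxa must not be labeled non-core")
  if (any(!object@taxa$is_core & object@taxa$label != "non-core"))
    msgs <- c(msgs, "non-core taxa must be labeled non-core")
  if (length(msgs)) msgs else TRUE
})

#' CooccurrenceNetwork: thresholded Spearman co-occurrence graph
#'
#' @slot graph an igraph object (undirected, no self loops).
#' @slot edges data.frame taxon_a, taxon_b, rho, p, sign.
#' @slot rThreshold,pThreshold thresholds used to keep edges.
#' @export
setClass("CooccurrenceNetwork",
  representation(graph = "ANY", edges = "data.frame",
                 rThreshold = "numeric", pThreshold = "numeric"))

setValidity("CooccurrenceNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$taxon_a == e$taxon_b)) msgs <- c(msgs, "self-edges not allowed")
    if (any(abs(e$rho) < object@rThreshold - 1e-12))
      msgs <- c(msgs, "edge below correlation threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' PathFit: fitted piecewise path model
#'
#' @slot spec the PathModelSpec (edge list) the fit was computed for.
#' @slot coefficients data.frame from, to, estimate, std_estimate, se, p.
#' @slot r2 named numeric, R^2 per endogenous variable.
#' @slot claims data.frame of d-separation independence claims with their
#'   p-values.
#' @slot fisherC,df,p Fisher's C statistic, its degrees of freedom (2k) and
#'   the chi-square upper-tail p-value.
#' @export
setClass("PathFit",
  representation(spec = "data.frame", coefficients = "data.frame",
                 r2 = "numeric", claims = "data.frame",
                 fisherC = "numeric", df = "numeric", p = "numeric"))

setValidity("PathFit", function(object) {
  msgs <- character()
  if (object@fisherC < 0) msgs <- c(msgs, "Fisher's C must be >= 0")
  if (object@df %% 2 != 0) msgs <- c(msgs, "df must be even (2 per claim)")
  if (length(msgs)) msgs else TRUE
})
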