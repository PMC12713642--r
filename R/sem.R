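#' Define a path-model specification
#'
#' An edge list of directed effects among observed variables. The graph
#' must be acyclic and free of duplicate edges.
#'
#' @param from,to character vectors of equal length (edges from -> to),
#'   or a single data.frame with columns from and to passed as
#'   \code{from}.
#' @return data.frame of class "PathModelSpec" with columns from, to.
#' @examples
#' pathModelSpec(c("pH", "core"), c("core", "structure"))
#' @export
pathModelSpec <- function(from, to = NULL) {
  spec <- if (is.data.frame(from)) from[, c("from", "to")]
          else data.frame(from = from, to = to, stringsAsFactors = FALSE)
  stopIfNot(!anyDuplicated(paste(spec$from, spec$to, sep = "\r")),
            "duplicate edges in the path model")
  stopIfNot(all(spec$from != spec$to), "self-loops are not allowed")
  topoSort(spec)  # errors on cycles
  class(spec) <- c("PathModelSpec", "data.frame")
  spec
}

#' Read a path-model spec from a two-column edge-list file
#'
#' @param path text file with tab-separated \code{from<TAB>to} lines
#'   (a header line "from\\tto" is allowed).
#' @return A \code{\link{pathModelSpec}}.
#' @export
readPathModelSpec <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, col.names = c("from", "to"))
  if (nrow(df) && identical(tolower(unlist(df[1, ])), c("from", "to")))
    df <- df[-1, , drop = FALSE]
  pathModelSpec(df$from, df$to)
}

## Kahn topological sort; errors on cycles. Returns all variables in a
## valid causal order (isolated/exogenous variables first by appearance).
topoSort <- function(spec) {
  vars <- unique(c(spec$from, spec$to))
  inDeg <- setNames(integer(length(vars)), vars)
  for (v in spec$to) inDeg[v] <- inDeg[v] + 1L
  order <- character(0)
  avail <- names(inDeg)[inDeg == 0]
  edges <- spec
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    kids <- edges$to[edges$from == v]
    edges <- edges[edges$from != v, , drop = FALSE]
    for (ch in kids) {
      inDeg[ch] <- inDeg[ch] - 1L
      if (inDeg[ch] == 0) avail <- c(avail, ch)
    }
  }
  stopIfNot(length(order) == length(vars),
            "path model contains a cycle")
  order
}

#' d-separation basis set of a path model
#'
#' Lists the independence claims tested by the piecewise approach: one
#' claim per non-adjacent variable pair, conditioned on the union of the
#' parents of both variables. The pair is ordered so the claim regresses
#' the causally later variable on the earlier one.
#'
#' @param spec a \code{\link{pathModelSpec}}.
#' @return data.frame: x, y (regress y on x), conditioning (comma-joined
#'   parent set, "" when empty). Zero rows for a saturated model.
#' @export
basisSet <- function(spec) {
  vars <- topoSort(spec)
  adj <- paste(spec$from, spec$to, sep = "\r")
  parents <- function(v) spec$from[spec$to == v]
  out <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    x <- vars[i]; y <- vars[j]
    if (paste(x, y, sep = "\r") %in% adj ||
        paste(y, x, sep = "\r") %in% adj) next
    cond <- setdiff(unique(c(parents(y), parents(x))), c(x, y))
    out[[length(out) + 1]] <- data.frame(
      x = x, y = y, conditioning = paste(cond, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(x = character(), y = character(),
                      conditioning = character()))
  do.call(rbind, out)
}

#' Fit a piecewise path model
#'
#' One ordinary least-squares regression per endogenous variable on its
#' parents; coefficients are standardised by sd(x)/sd(y). Each
#' independence claim of the \code{\link{basisSet}} is tested by the
#' partial-regression t-test of x in \code{y ~ x + conditioning set};
#' Fisher's \code{C = -2 sum(log p)} combines the claim p-values and is
#' referred to a chi-square with \code{2k} degrees of freedom.
#'
#' @param spec a \code{\link{pathModelSpec}}.
#' @param data data.frame containing every model variable.
#' @return A \linkS4class{PathFit}.
#' @export
fitPaths <- function(spec, data) {
  vars <- topoSort(spec)
  miss <- setdiff(vars, names(data))
  stopIfNot(length(miss) == 0,
            paste0("variables missing from data: ",
                   paste(miss, collapse = ", ")))
  endo <- unique(spec$to)
  coefs <- list(); r2 <- setNames(numeric(0), character(0))
  for (v in endo) {
    par <- spec$from[spec$to == v]
    stopIfNot(nrow(data) > length(par) + 2,
              paste0("too few observations for component model of ", v))
    form <- as.formula(paste(v, "~", paste(par, collapse = " + ")))
    fit <- lm(form, data = data)
    if (any(is.na(coef(fit))))
      stop(paste0("singular design in the component model of ", v),
           call. = FALSE)
    sm <- summary(fit)
    b <- coef(sm)
    for (p in par)
      coefs[[length(coefs) + 1]] <- data.frame(
        from = p, to = v, estimate = b[p, "Estimate"],
        std_estimate = b[p, "Estimate"] * sd(data[[p]]) / sd(data[[v]]),
        se = b[p, "Std. Error"], p = b[p, "Pr(>|t|)"],
        stringsAsFactors = FALSE)
    r2[v] <- sm$r.squared
  }
  bs <- basisSet(spec)
  claims <- bs
  claims$p <- rep(NA_real_, nrow(bs))
  if (nrow(bs)) for (k in seq_len(nrow(bs))) {
    cond <- strsplit(bs$conditioning[k], ",")[[1]]
    cond <- cond[nzchar(cond)]
    rhs <- paste(c(bs$x[k], cond), collapse = " + ")
    fit <- lm(as.formula(paste(bs$y[k], "~", rhs)), data = data)
    claims$p[k] <- coef(summary(fit))[bs$x[k], "Pr(>|t|)"]
  }
  C <- if (nrow(claims)) -2 * sum(log(pmax(claims$p, 1e-300))) else 0
  dfC <- 2 * nrow(claims)
  pC <- if (dfC > 0) pchisq(C, dfC, lower.tail = FALSE) else 1
  new("PathFit", spec = as.data.frame(spec),
      coefficients = if (length(coefs)) do.call(rbind, coefs)
                     else data.frame(),
      r2 = r2, claims = claims, fisherC = C, df = dfC, p = pC)
}

#' Accept or reject a path-model fit
#'
#' The model is accepted when it is saturated (df = 0) or when
#' \code{FisherC/df <= 2} and \code{p > 0.05}.
#'
#' @param fit a \linkS4class{PathFit}.
#' @return Logical: TRUE = accept.
#' @export
evaluateFit <- function(fit) {
  if (fit@df == 0) return(TRUE)
  (fit@fisherC / fit@df) <= 2 && fit@p > 0.05
}
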