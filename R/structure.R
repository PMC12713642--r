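#' Bray-Curtis dissimilarity matrix
#'
#' \code{d(x, y) = 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i)}. Defined
#' for counts or relative abundances; a pair of all-zero samples has no
#' defined dissimilarity and raises an error naming the pair.
#'
#' @param tab an \linkS4class{AbundanceTable}.
#' @return A \code{dist} object over the samples.
#' @export
brayCurtis <- function(tab) {
  stopIfNot(is(tab, "AbundanceTable"), "input must be an AbundanceTable")
  v <- abundances(tab)
  zero <- rowSums(v) == 0
  if (sum(zero) >= 2)
    stop(paste0("Bray-Curtis undefined between all-zero samples: ",
                paste(head(rownames(v)[zero], 5), collapse = ", ")),
         call. = FALSE)
  vegan::vegdist(v, method = "bray")
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Iterative stress minimisation: at each step the fitted distances are
#' replaced by their isotonic regression on the observed dissimilarity
#' order (primary tie handling: tied dissimilarities are free to order by
#' current configuration distance) and the configuration is moved by a
#' Guttman-transform step, halved as needed so that stress-1 never
#' increases within a run. The best of \code{nRestarts} starts is
#' returned (the first start is the principal-coordinate configuration,
#' the rest are seeded random starts).
#'
#' @param d a \code{dist} object or square symmetric matrix.
#' @param k embedding dimension (default 2).
#' @param nRestarts number of starts (default 20).
#' @param maxIter iterations per run (default 300).
#' @param tol stop a run when stress improves by less than this
#'   (default 1e-7).
#' @param seed integer seed for the random starts.
#' @return A list with \code{points} (n x k, centered at the origin),
#'   \code{stress} (Kruskal stress-1 of the best run), \code{trace}
#'   (stress per iteration of the best run, non-increasing),
#'   \code{allTraces} (one stress trace per restart), \code{converged}.
#' @export
nmds <- function(d, k = 2, nRestarts = 20, maxIter = 300, tol = 1e-7,
                 seed = 1) {
  D <- as.matrix(d)
  n <- nrow(D)
  stopIfNot(n >= k + 2, "need at least k + 2 samples")
  dvec <- D[lower.tri(D)]
  ordBase <- order(dvec)

  stressOf <- function(X) {
    dx <- dist(X)
    dhat <- .monotoneFit(dvec, dx)
    sqrt(sum((dx - dhat)^2) / sum(dx^2))
  }

  runOne <- function(X) {
    X <- scale(X, scale = FALSE)
    s <- stressOf(X)
    trace <- s
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      dx <- dist(X)
      dhat <- .monotoneFit(dvec, dx)
      ## Guttman transform towards the disparities
      B <- matrix(0, n, n)
      dxm <- as.matrix(dx)
      dhm <- matrix(0, n, n)
      dhm[lower.tri(dhm)] <- dhat
      dhm <- dhm + t(dhm)
      ratio <- ifelse(dxm > 1e-12, dhm / dxm, 0)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      Xnew <- (B %*% X) / n
      Xnew <- scale(Xnew, scale = FALSE)
      sNew <- stressOf(Xnew)
      step <- 1
      while (sNew > s && step > 1e-4) {  # guarantee monotone stress
        step <- step / 2
        Xtry <- X + step * (Xnew - X)
        sNew <- stressOf(Xtry)
        if (sNew <= s) Xnew <- Xtry
      }
      if (sNew > s) { conv <- TRUE; break }
      X <- scale(Xnew, scale = FALSE)
      if (s - sNew < tol) { s <- sNew; trace <- c(trace, sNew); conv <- TRUE; break }
      s <- sNew
      trace <- c(trace, sNew)
    }
    list(points = X, stress = s, trace = trace, converged = conv)
  }

  ## start 1: classical scaling; remaining: seeded random configurations
  starts <- withSeed(seed, {
    st <- list(suppressWarnings(cmdscale(D, k = k)))
    for (r in seq_len(max(0, nRestarts - 1)))
      st[[r + 1]] <- matrix(rnorm(n * k), n, k)
    st
  })
  runs <- lapply(starts, runOne)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "stress"))]]
  best$allTraces <- lapply(runs, `[[`, "trace")
  rownames(best$points) <- rownames(D)
  if (!best$converged)
    warning("NMDS did not converge in any restart; returning best found")
  best
}

## isotonic regression of configuration distances on the dissimilarity
## order; ties in the dissimilarities are pre-sorted by current distance
## (Kruskal's primary approach), so no constraint binds within a tie block
.monotoneFit <- function(dvec, dx) {
  dx <- as.numeric(dx)
  o <- order(dvec, dx)
  fit <- isoreg(dx[o])$yf
  out <- numeric(length(dx))
  out[o] <- fit
  out
}

#' PERMANOVA (distance-based permutation ANOVA)
#'
#' Pseudo-F from the Gower-centered sum-of-squares partition of a
#' distance matrix by a grouping factor, with a permutation p-value
#' \code{p = (#(F_perm >= F_obs) + 1) / (nPerms + 1)}. Computed with
#' \code{vegan::adonis2} under a fixed seed.
#'
#' @param d a \code{dist} object.
#' @param groups grouping labels (>= 2 groups of >= 2 samples).
#' @param nPerms number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: F, R2, p, n_perms.
#' @export
permanova <- function(d, groups, nPerms = 999, seed = 1) {
  groups <- factor(groups)
  stopIfNot(nlevels(groups) >= 2, "need at least 2 groups")
  stopIfNot(all(table(groups) >= 2), "every group needs >= 2 samples")
  df <- data.frame(groups = groups)
  res <- withSeed(seed,
    vegan::adonis2(d ~ groups, data = df, permutations = nPerms))
  data.frame(F = res$F[1], R2 = res$R2[1], p = res$`Pr(>F)`[1],
             n_perms = nPerms)
}

#' Pairwise PERMANOVA with Holm adjustment
#'
#' Runs \code{\link{permanova}} on every pair of groups and adjusts the
#' permutation p-values with Holm's method.
#'
#' @inheritParams permanova
#' @return data.frame: pair, F, R2, p, p_adj.
#' @export
pairwisePermanova <- function(d, groups, nPerms = 999, seed = 1) {
  groups <- factor(groups)
  D <- as.matrix(d)
  prs <- combn(levels(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    idx <- groups %in% prs[, k]
    r <- permanova(as.dist(D[idx, idx]), droplevels(groups[idx]),
                   nPerms = nPerms, seed = stageSeed(seed, paste(prs[, k],
                                                    collapse = "|")))
    cbind(pair = paste(prs[1, k], prs[2, k], sep = " vs "), r)
  }))
  out$p_adj <- p.adjust(out$p, "holm")
  out
}

#' PERMANOVA with covariates (sequential terms)
#'
#' Sequential (Type I) single-term partition of the distance matrix over
#' the given model terms, in order, via \code{vegan::adonis2(by =
#' "terms")}.
#'
#' @param d a \code{dist} object.
#' @param meta data.frame of covariates aligned with \code{d}.
#' @param terms character vector of column names, fitted in this order.
#' @param nPerms,seed as in \code{\link{permanova}}.
#' @return data.frame: term, F, R2, p.
#' @export
permanovaTerms <- function(d, meta, terms, nPerms = 999, seed = 1) {
  stopIfNot(all(terms %in% names(meta)), "terms must be metadata columns")
  form <- as.formula(paste("d ~", paste(terms, collapse = " + ")))
  res <- withSeed(seed,
    vegan::adonis2(form, data = meta, permutations = nPerms, by = "terms"))
  keep <- !rownames(res) %in% c("Residual", "Total")
  data.frame(term = rownames(res)[keep], F = res$F[keep],
             R2 = res$R2[keep], p = res$`Pr(>F)`[keep], row.names = NULL)
}

#' Within-group beta dispersion
#'
#' Distance of each sample to its group centroid in the
#' principal-coordinate embedding of the distance matrix (negative
#' eigenvalues handled by the imaginary-part correction of
#' \code{vegan::betadisper}), plus each group's mean ("Disp").
#'
#' @param d a \code{dist} object.
#' @param groups grouping labels, every group with >= 2 samples.
#' @return list with \code{samples} (sample_id, group, dist_to_centroid)
#'   and \code{groups} (group, disp).
#' @export
betaDispersion <- function(d, groups) {
  groups <- factor(groups)
  stopIfNot(all(table(groups) >= 2), "every group needs >= 2 samples")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  samples <- data.frame(sample_id = attr(d, "Labels"),
                        group = as.character(groups),
                        dist_to_centroid = as.numeric(bd$distances),
                        stringsAsFactors = FALSE)
  byGroup <- aggregate(dist_to_centroid ~ group, samples, mean)
  names(byGroup) <- c("group", "disp")
  list(samples = samples, groups = byGroup)
}

#' Distance between two group centroids
#'
#' Euclidean distance between group centroids in the
#' principal-coordinate embedding, computed directly from the distance
#' matrix via the centroid identity
#' \code{|cA - cB|^2 = mean(d^2 across) - mean(d^2 within A)/2 -
#' mean(d^2 within B)/2}, which carries the negative-eigenvalue
#' (imaginary part) correction automatically.
#'
#' @param d a \code{dist} object.
#' @param groups grouping labels.
#' @param pair character vector of the two group labels.
#' @return Numeric centroid distance.
#' @export
centroidDistance <- function(d, groups, pair) {
  stopIfNot(length(pair) == 2 && all(pair %in% groups),
            "pair must name two groups present in 'groups'")
  D2 <- as.matrix(d)^2
  a <- which(groups == pair[1])
  b <- which(groups == pair[2])
  v <- mean(D2[a, b, drop = FALSE]) -
    sum(D2[a, a]) / (2 * length(a)^2) -
    sum(D2[b, b]) / (2 * length(b)^2)
  sqrt(max(v, 0))
}

#' Mantel test
#'
#' Pearson correlation of the lower triangles of two distance matrices
#' over the same samples; one-sided (greater) permutation p-value from
#' permuting the sample labels of the second matrix.
#'
#' @param d1,d2 \code{dist} objects over the same sample set and order.
#' @param nPerms number of permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: r, p, n_perms.
#' @export
mantelTest <- function(d1, d2, nPerms = 999, seed = 1) {
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2))
    stopIfNot(identical(l1, l2), "distance matrices cover different samples")
  stopIfNot(attr(d1, "Size") == attr(d2, "Size"),
            "distance matrices differ in size")
  res <- withSeed(seed,
    vegan::mantel(d1, d2, method = "pearson", permutations = nPerms))
  data.frame(r = res$statistic, p = res$signif, n_perms = nPerms)
}
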