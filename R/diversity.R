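#' Observed richness of a sample
#'
#' @param sample numeric abundance vector.
#' @return Number of taxa with abundance > 0.
#' @export
richness <- function(sample) sum(sample > 0)

#' Inverse Simpson index
#'
#' \code{1 / sum(p_i^2)} with p the within-sample relative abundances.
#' Equals 1 for a single-taxon sample and reaches the richness exactly at
#' the uniform composition.
#'
#' @param sample numeric abundance vector with at least one positive entry.
#' @return Inverse Simpson diversity.
#' @export
inverseSimpson <- function(sample) {
  tot <- sum(sample)
  stopIfNot(tot > 0, "inverse Simpson is undefined for an all-zero sample")
  p <- sample / tot
  1 / sum(p^2)
}

## parent-pointer map of a phylo object: parent[node] (0 for the root)
.parentMap <- function(tree) {
  nNode <- max(tree$edge)
  parent <- integer(nNode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal rooted subtree spanning the taxa
#' present in the sample, including the path to the root (so a single tip
#' scores its root-to-tip distance).
#'
#' @param sample named abundance vector, or a character vector of present
#'   taxon names.
#' @param tree rooted \code{ape::phylo} with branch lengths; all present
#'   taxa must be tips.
#' @return PD in branch-length units (0 for an empty sample).
#' @export
faithPD <- function(sample, tree) {
  present <- if (is.character(sample)) sample else {
    stopIfNot(!is.null(names(sample)), "sample vector must be named by taxon")
    names(sample)[sample > 0]
  }
  if (!length(present)) return(0)
  miss <- setdiff(present, tree$tip.label)
  stopIfNot(length(miss) == 0,
            paste0("taxa absent from the tree: ",
                   paste(head(miss, 10), collapse = ", ")))
  parent <- .parentMap(tree)
  keep <- logical(max(tree$edge))
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != 0 && !keep[node]) {
      keep[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[keep[tree$edge[, 2]]])
}

#' Net relatedness index (NRI)
#'
#' Standardised effect size of the unweighted mean pairwise patristic
#' distance (MPD) among the taxa present in a sample, against a null of
#' shuffling tip labels across the whole tree:
#' \code{NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)}. Positive NRI
#' means phylogenetic clustering.
#'
#' @param sample named abundance vector (presence is abundance > 0).
#' @param tree rooted \code{ape::phylo}.
#' @param nNull number of tip-label shuffles (>= 99; default 999).
#' @param seed integer seed for the null draws.
#' @return NRI (unitless).
#' @export
nri <- function(sample, tree, nNull = 999, seed = 1) {
  stopIfNot(!is.null(names(sample)), "sample vector must be named by taxon")
  present <- names(sample)[sample > 0]
  stopIfNot(length(present) >= 2, "NRI needs at least 2 present taxa")
  stopIfNot(nNull >= 99, "use at least 99 null shuffles")
  miss <- setdiff(present, tree$tip.label)
  stopIfNot(length(miss) == 0,
            paste0("taxa absent from the tree: ",
                   paste(head(miss, 10), collapse = ", ")))
  D <- ape::cophenetic.phylo(tree)
  idx <- match(present, rownames(D))
  mpd <- function(i) mean(D[i, i][lower.tri(matrix(0, length(i), length(i)))])
  obs <- mpd(idx)
  nTip <- length(tree$tip.label)
  nulls <- withSeed(seed, vapply(seq_len(nNull), function(r) {
    mpd(sample.int(nTip, length(present)))
  }, numeric(1)))
  s <- sd(nulls)
  stopIfNot(s > 0, "degenerate null: MPD has zero variance under shuffling")
  -(obs - mean(nulls)) / s
}

#' Per-sample diversity profile
#'
#' Computes richness, inverse Simpson, Faith PD and (optionally) NRI for
#' every sample of a table.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param tree optional rooted tree; when NULL the phylogenetic columns
#'   are skipped.
#' @param nNull,seed passed to \code{\link{nri}}.
#' @return data.frame with one row per sample.
#' @export
diversityProfile <- function(tab, tree = NULL, nNull = 999, seed = 1) {
  assertCounts(tab, "diversityProfile")
  v <- abundances(tab)
  out <- data.frame(sample_id = rownames(v),
                    richness = apply(v, 1, richness),
                    inverse_simpson = apply(v, 1, function(x)
                      if (sum(x) > 0) inverseSimpson(x) else 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree)) {
    out$faith_pd <- apply(v, 1, faithPD, tree = tree)
    out$nri <- vapply(seq_len(nrow(v)), function(i)
      nri(v[i, ], tree, nNull = nNull, seed = stageSeed(seed, rownames(v)[i])),
      numeric(1))
  }
  out
}

#' Habitat effect test with Type II ANOVA and Tukey contrasts
#'
#' Fits \code{value ~ habitat * site} (the interaction is dropped when
#' not estimable), reports Type II F tests for each term, and all
#' pairwise habitat contrasts with Tukey (studentized-range) familywise
#' adjustment on the marginal habitat means.
#'
#' @param values numeric vector, one value per sample.
#' @param meta metadata data.frame with habitat and site columns aligned
#'   with \code{values} (a \code{sample_id} column is allowed but not
#'   required here).
#' @return A list with \code{anova} (term, F, p) and \code{contrasts}
#'   (pair, estimate, p_adj).
#' @export
habitatEffectTest <- function(values, meta) {
  stopIfNot(length(values) == nrow(meta),
            "values and metadata differ in length")
  df <- data.frame(value = values,
                   habitat = factor(meta$habitat),
                   site = factor(meta$site))
  stopIfNot(nlevels(df$habitat) >= 2 &&
              all(table(df$habitat) >= 2),
            "need >= 2 habitats with >= 2 samples each")
  if (var(values) == 0) {
    terms <- c("habitat", "site", "habitat:site")
    prs <- combn(levels(df$habitat), 2)
    return(list(
      anova = data.frame(term = terms, F = 0, p = 1),
      contrasts = data.frame(pair = paste(prs[1, ], prs[2, ], sep = " - "),
                             estimate = 0, p_adj = 1)))
  }
  cells <- table(df$habitat, df$site)
  useInt <- nlevels(df$site) > 1 && all(cells > 0) &&
    sum(cells > 1) > (nlevels(df$habitat) + nlevels(df$site) - 1)
  form <- if (useInt) value ~ habitat * site else
    if (nlevels(df$site) > 1) value ~ habitat + site else value ~ habitat
  fit <- lm(form, data = df)
  if (any(is.na(coef(fit))))
    stop(paste0("rank-deficient design; aliased: ",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  aov2 <- car::Anova(fit, type = 2)
  keep <- rownames(aov2) != "Residuals"
  anovaTab <- data.frame(term = rownames(aov2)[keep],
                         F = aov2$`F value`[keep],
                         p = aov2$`Pr(>F)`[keep], row.names = NULL)

  ## Tukey HSD on marginal (site-averaged) habitat means
  mm <- model.matrix(fit)
  X <- mm
  beta <- coef(fit)
  levs <- levels(df$habitat)
  ## marginal mean of habitat h = average prediction over observed sites
  marg <- vapply(levs, function(h) {
    nd <- expand.grid(habitat = factor(h, levels = levs),
                      site = factor(levels(df$site),
                                    levels = levels(df$site)))
    if (!"site" %in% all.vars(form)) nd <- nd[1, , drop = FALSE]
    Xh <- model.matrix(delete.response(terms(fit)), nd)
    colMeans(Xh)
  }, numeric(length(beta)))
  V <- vcov(fit)
  dfRes <- fit$df.residual
  prs <- combn(levs, 2)
  est <- se <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    cvec <- marg[, prs[1, k]] - marg[, prs[2, k]]
    est[k] <- sum(cvec * beta)
    se[k] <- sqrt(drop(t(cvec) %*% V %*% cvec))
  }
  tval <- est / se
  pAdj <- ptukey(abs(tval) * sqrt(2), nmeans = length(levs), df = dfRes,
                 lower.tail = FALSE)
  list(anova = anovaTab,
       contrasts = data.frame(pair = paste(prs[1, ], prs[2, ], sep = " - "),
                              estimate = est, se = se, t = tval,
                              p_adj = pAdj, row.names = NULL))
}
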