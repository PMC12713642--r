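#' Habitat-overlap categories
#'
#' Classifies every taxon by its presence pattern across the three
#' habitats: unique to one habitat, shared between two, or present in all
#' three. Presence means count > 0 in at least one sample of the habitat.
#' Taxa absent everywhere are excluded with a warning.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param meta metadata with sample_id and habitat.
#' @return data.frame: taxon, category (e.g. "soil only",
#'   "litter+sphagnum", "all three"), plus one logical column per habitat.
#' @export
habitatOverlap <- function(tab, meta) {
  assertCounts(tab, "habitatOverlap")
  meta <- alignMeta(tab, meta)
  stopIfNot(all(HABITATS %in% meta$habitat),
            "all three habitats must be present")
  v <- abundances(tab)
  pres <- vapply(HABITATS, function(h)
    colSums(v[meta$habitat == h, , drop = FALSE] > 0) > 0,
    logical(ncol(v)))
  nHab <- rowSums(pres)
  if (any(nHab == 0))
    warning(sum(nHab == 0), " taxa absent from every sample were excluded")
  cat <- ifelse(nHab == 3, "all three",
                ifelse(nHab == 1,
                       paste(HABITATS[apply(pres, 1, which.max)], "only"),
                       apply(pres, 1, function(z)
                         paste(HABITATS[z], collapse = "+"))))
  out <- data.frame(taxon = colnames(v), category = cat, pres,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[nHab > 0, , drop = FALSE]
}

#' Detect the host core microbiome
#'
#' A taxon is core iff its mean relative abundance across host samples is
#' at least \code{minRA} and it is present (count > 0) in at least
#' \code{minPrev} of the host samples. Both thresholds are inclusive; the
#' comparison uses a 1e-9 relative floating-point guard so that a mean
#' mathematically equal to the threshold always passes.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param meta metadata with sample_id and habitat.
#' @param host host habitat (default "sphagnum"); must have >= 5 samples.
#' @param minRA minimum mean host relative abundance (default 0.001,
#'   i.e. 0.1\%).
#' @param minPrev minimum host prevalence (default 0.8).
#' @param perSampleRA if TRUE, require every host sample (not the mean)
#'   to reach \code{minRA}.
#' @return data.frame: taxon, host_prevalence, host_mean_ra, is_core.
#' @export
detectCore <- function(tab, meta, host = "sphagnum", minRA = 0.001,
                       minPrev = 0.8, perSampleRA = FALSE) {
  assertCounts(tab, "detectCore")
  meta <- alignMeta(tab, meta)
  hostIdx <- which(meta$habitat == host)
  stopIfNot(length(hostIdx) >= 5, "host habitat needs >= 5 samples")
  v <- abundances(tab)[hostIdx, , drop = FALSE]
  rel <- v / pmax(rowSums(v), 1)
  prev <- colMeans(v > 0)
  meanRA <- colMeans(rel)
  tol <- function(x, thr) x >= thr * (1 - 1e-9)
  raOK <- if (perSampleRA) apply(rel, 2, function(x) all(tol(x, minRA)))
          else tol(meanRA, minRA)
  data.frame(taxon = colnames(v), host_prevalence = prev,
             host_mean_ra = meanRA,
             is_core = raOK & tol(prev, minPrev),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a zero-inflated beta model of relative abundance by group
#'
#' Two-part model fitted by maximum likelihood via glmmTMB: a logistic
#' zero mass (logit(pi) ~ group) and a beta component for the positive
#' abundances (logit(mu) ~ group, constant precision phi). Values equal
#' to 1 are squeezed to (n - 0.5)/n before the beta part.
#'
#' @param y relative abundances in [0, 1), one per sample.
#' @param groups habitat labels aligned with \code{y}; the first level of
#'   \code{factor(groups, levels = unique(...))} is the reference.
#' @param ref optional reference level (e.g. the host habitat).
#' @return A list of class "ZIBFit": model (glmmTMB fit or NULL), pi and
#'   mu per group, phi, logLik, degenerate flag, group levels.
#' @export
fitZIB <- function(y, groups, ref = NULL) {
  stopIfNot(all(y >= 0 & y <= 1), "y must lie in [0, 1]")
  g <- factor(groups)
  if (!is.null(ref)) g <- stats::relevel(g, ref = ref)
  stopIfNot(all(table(g) >= 3), "need >= 3 samples per group")
  n <- length(y)
  y <- ifelse(y >= 1, (n - 0.5) / n, y)
  if (all(y == 0))
    return(structure(list(model = NULL, degenerate = TRUE,
                          reason = "all observations zero",
                          levels = levels(g)), class = "ZIBFit"))
  anyZero <- any(y == 0)
  zf <- if (!anyZero) ~0 else if (all(tapply(y > 0, g, any)) &&
                                    all(tapply(y == 0, g, any))) ~group
        else ~1
  dat <- data.frame(y = y, group = g)
  fit <- tryCatch(
    glmmTMB::glmmTMB(y ~ group, ziformula = zf, data = dat,
                     family = glmmTMB::beta_family()),
    error = function(e) e, warning = function(w)
      suppressWarnings(glmmTMB::glmmTMB(y ~ group, ziformula = zf,
                                        data = dat,
                                        family = glmmTMB::beta_family())))
  if (inherits(fit, "error"))
    stop("zero-inflated beta fit failed: ", conditionMessage(fit),
         call. = FALSE)
  lv <- levels(g)
  nd <- data.frame(group = factor(lv, levels = lv))
  mu <- tryCatch(stats::predict(fit, newdata = nd, type = "conditional"),
                 error = function(e) rep(NA_real_, length(lv)))
  pi <- tryCatch(stats::predict(fit, newdata = nd, type = "zprob"),
                 error = function(e) rep(NA_real_, length(lv)))
  emptyGroups <- names(which(tapply(y > 0, g, sum) == 0))
  structure(list(model = fit, degenerate = FALSE,
                 pi = setNames(as.numeric(pi), lv),
                 mu = setNames(as.numeric(mu), lv),
                 phi = glmmTMB::sigma(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 empty_groups = emptyGroups,
                 levels = lv), class = "ZIBFit")
}

#' Wald contrasts of the beta mean against a reference group
#'
#' Computes reference-vs-other contrasts on the logit(mu) scale from a
#' \code{\link{fitZIB}} fit, with familywise adjustment across the
#' contrast family: "mvn" (default) is the single-step multivariate
#' normal (Tukey-style) adjustment computed with the deterministic Miwa
#' algorithm; "holm" is the step-down Bonferroni fallback.
#'
#' @param fit a ZIBFit whose reference level is the group of interest.
#' @param adjust "mvn" or "holm".
#' @return data.frame: contrast ("ref - other"), estimate (logit scale,
#'   positive = higher in reference), se, z, p, p_adj. Contrasts against
#'   groups with no positive observations are returned as NA.
#' @export
zibContrasts <- function(fit, adjust = c("mvn", "holm")) {
  adjust <- match.arg(adjust)
  stopIfNot(inherits(fit, "ZIBFit"), "fit must come from fitZIB")
  lv <- fit$levels
  out <- data.frame(contrast = paste(lv[1], "-", lv[-1]),
                    estimate = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  if (fit$degenerate || is.null(fit$model)) return(out)
  beta <- glmmTMB::fixef(fit$model)$cond
  V <- vcov(fit$model)$cond
  idx <- match(paste0("group", lv[-1]), names(beta))
  ok <- !is.na(idx) & !(lv[-1] %in% fit$empty_groups)
  est <- -beta[idx]          # ref minus other on the logit(mu) scale
  se <- sqrt(diag(V)[idx])
  z <- est / se
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  out$estimate <- as.numeric(est)
  out$se <- as.numeric(se)
  out$z <- as.numeric(z)
  out$p <- as.numeric(p)
  out$estimate[!ok] <- out$se[!ok] <- out$z[!ok] <- out$p[!ok] <- NA
  okIdx <- which(ok)
  if (length(okIdx) == 1) {
    out$p_adj[okIdx] <- out$p[okIdx]
  } else if (length(okIdx) > 1) {
    if (adjust == "holm") {
      out$p_adj[okIdx] <- p.adjust(out$p[okIdx], "holm")
    } else {
      Vc <- V[idx[okIdx], idx[okIdx]]
      R <- stats::cov2cor(Vc)
      zz <- out$z[okIdx]
      out$p_adj[okIdx] <- vapply(zz, function(zk) {
        1 - mvtnorm::pmvnorm(lower = rep(-abs(zk), length(zz)),
                             upper = rep(abs(zk), length(zz)),
                             corr = R,
                             algorithm = mvtnorm::Miwa(steps = 512))[1]
      }, numeric(1))
      out$p_adj[okIdx] <- pmin(pmax(out$p_adj[okIdx], 0), 1)
    }
  }
  out
}

#' Stratify the core microbiome into SU / ES / EC
#'
#' For each core taxon: \strong{SU} (host-unique) if it has zero counts
#' in every non-host sample; otherwise \strong{ES} (host-enriched) if
#' both host-vs-other-habitat contrasts from the zero-inflated beta model
#' are significant at \code{alpha} (familywise-adjusted) with a higher
#' host mean; otherwise \strong{EC} (environmental core) if present in
#' all three habitats; otherwise \strong{core-unresolved} (present in
#' exactly two habitats, not enriched). Non-core taxa are labeled
#' "non-core". SU + ES form the host-specific core.
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param meta metadata with sample_id and habitat.
#' @param core data.frame from \code{\link{detectCore}} (or NULL to
#'   compute it with default thresholds).
#' @param host host habitat, default "sphagnum".
#' @param alpha significance level for the enrichment contrasts.
#' @param adjust contrast adjustment, "mvn" (default) or "holm".
#' @param minRA,minPrev passed to \code{\link{detectCore}} when
#'   \code{core} is NULL.
#' @return A \linkS4class{CoreClassification}.
#' @export
classifyCore <- function(tab, meta, core = NULL, host = "sphagnum",
                         alpha = 0.05, adjust = c("mvn", "holm"),
                         minRA = 0.001, minPrev = 0.8) {
  adjust <- match.arg(adjust)
  assertCounts(tab, "classifyCore")
  meta <- alignMeta(tab, meta)
  if (is.null(core))
    core <- detectCore(tab, meta, host = host, minRA = minRA,
                       minPrev = minPrev)
  v <- abundances(tab)
  rel <- v / pmax(rowSums(v), 1)
  others <- setdiff(HABITATS, host)
  hab <- meta$habitat
  tx <- data.frame(taxon = core$taxon, is_core = core$is_core,
                   label = "non-core",
                   host_prevalence = core$host_prevalence,
                   host_mean_ra = core$host_mean_ra,
                   p_vs_litter = NA_real_, p_vs_soil = NA_real_,
                   stringsAsFactors = FALSE)
  pCols <- paste0("p_vs_", others)
  for (i in which(tx$is_core)) {
    taxon <- tx$taxon[i]
    cnt <- v[, taxon]
    presHab <- vapply(HABITATS, function(h) any(cnt[hab == h] > 0),
                      logical(1))
    if (all(cnt[hab != host] == 0)) {
      tx$label[i] <- "SU"
      next
    }
    zib <- tryCatch(fitZIB(rel[, taxon], hab, ref = host),
                    error = function(e) NULL)
    ctr <- if (!is.null(zib)) zibContrasts(zib, adjust = adjust) else NULL
    enriched <- FALSE
    if (!is.null(ctr)) {
      for (h in others) {
        row <- ctr[ctr$contrast == paste(host, "-", h), ]
        tx[i, paste0("p_vs_", h)] <- row$p_adj
      }
      pA <- tx[i, pCols[1]]; pB <- tx[i, pCols[2]]
      eA <- ctr$estimate[ctr$contrast == paste(host, "-", others[1])]
      eB <- ctr$estimate[ctr$contrast == paste(host, "-", others[2])]
      enriched <- !is.na(pA) && !is.na(pB) && pA < alpha && pB < alpha &&
        !is.na(eA) && !is.na(eB) && eA > 0 && eB > 0
    }
    tx$label[i] <- if (enriched) "ES"
                   else if (all(presHab)) "EC"
                   else "core-unresolved"
  }
  new("CoreClassification", host = host, minRA = minRA,
      minPrev = minPrev, alpha = alpha, taxa = tx)
}

#' Summed relative abundance of a core group per sample
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param classification a \linkS4class{CoreClassification}.
#' @param grouping one of "total-core", "SU+ES", "EC".
#' @return data.frame: sample_id, abundance (summed relative abundance of
#'   the group's taxa in that sample).
#' @export
groupAbundance <- function(tab, classification,
                           grouping = c("total-core", "SU+ES", "EC")) {
  grouping <- match.arg(grouping)
  assertCounts(tab, "groupAbundance")
  v <- abundances(tab)
  rel <- v / pmax(rowSums(v), 1)
  tx <- classification@taxa
  members <- switch(grouping,
    "total-core" = tx$taxon[tx$is_core],
    "SU+ES" = tx$taxon[tx$label %in% c("SU", "ES")],
    "EC" = tx$taxon[tx$label == "EC"])
  members <- intersect(members, colnames(rel))
  ab <- if (length(members))
    rowSums(rel[, members, drop = FALSE]) else rep(0, nrow(rel))
  data.frame(sample_id = rownames(rel), abundance = as.numeric(ab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Core-group shares of ASV count and of summed core abundance
#'
#' @param tab counts-mode \linkS4class{AbundanceTable}.
#' @param classification a \linkS4class{CoreClassification}.
#' @return data.frame with one row per group (SU, ES, EC,
#'   core-unresolved): n_taxa, share_of_core_count, share_of_core_abundance
#'   (shares in percent, summing to 100 across groups).
#' @export
coreGroupShares <- function(tab, classification) {
  assertCounts(tab, "coreGroupShares")
  v <- abundances(tab)
  rel <- v / pmax(rowSums(v), 1)
  tx <- classification@taxa[classification@taxa$is_core, ]
  groups <- c("SU", "ES", "EC", "core-unresolved")
  totAb <- sum(colSums(rel[, tx$taxon, drop = FALSE]))
  out <- do.call(rbind, lapply(groups, function(gp) {
    mem <- tx$taxon[tx$label == gp]
    ab <- if (length(mem)) sum(colSums(rel[, mem, drop = FALSE])) else 0
    data.frame(group = gp, n_taxa = length(mem),
               share_of_core_count = 100 * length(mem) / nrow(tx),
               share_of_core_abundance = if (totAb > 0) 100 * ab / totAb
                                         else 0)
  }))
  out
}
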