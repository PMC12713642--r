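#' Pipeline configuration
#'
#' All thresholds and replication settings of \code{\link{runPipeline}},
#' with the host-system defaults: core thresholds 0.1\% mean relative
#' abundance and 80\% prevalence, alpha 0.05, 999 permutations, network
#' thresholds |rho| >= 0.6 at p <= 0.05. Every stochastic stage receives
#' a seed derived deterministically from the master seed.
#'
#' @param seed master seed.
#' @param host host habitat.
#' @param minReads rare-taxon filter (total reads).
#' @param depth rarefaction depth or "auto" (minimum sample total).
#' @param minRA,minPrev,alpha core detection / classification settings.
#' @param rThreshold,pThreshold network thresholds.
#' @param nullReps connectedness null shuffles.
#' @param nPerms permutations for PERMANOVA / Mantel.
#' @param nriReps NRI tip shuffles.
#' @param nmdsRestarts NMDS restarts.
#' @param robustnessOrders random removal orders.
#' @param nBootRobustness bootstrap replicates for the robustness
#'   regressions.
#' @param computeNRI set FALSE to skip phylogenetic metrics (no tree).
#' @param exclude taxa to drop before filtering (e.g. contaminants).
#' @return A list of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 42, host = "sphagnum", minReads = 10,
                           depth = "auto", minRA = 0.001, minPrev = 0.8,
                           alpha = 0.05, rThreshold = 0.6,
                           pThreshold = 0.05, nullReps = 200, nPerms = 999,
                           nriReps = 999, nmdsRestarts = 20,
                           robustnessOrders = 100, nBootRobustness = 20,
                           computeNRI = TRUE, exclude = NULL) {
  structure(as.list(environment()), class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full stratified-core analysis pipeline
#'
#' Executes preprocessing, diversity, cohesion/network, neutral-model
#' fits per habitat, core stratification, community-structure statistics,
#' stability regressions and path models, returning a result bundle and
#' (optionally) writing all outputs plus a reproducibility manifest.
#' Identical inputs + config produce an identical bundle and
#' byte-identical manifest.
#'
#' @param counts counts-mode \linkS4class{AbundanceTable}.
#' @param meta metadata data.frame (sample_id, habitat, site, plot, and
#'   optionally pH, elevation, pathway_carbon_energy).
#' @param tree optional rooted \code{ape::phylo} covering the taxa.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory for TSVs + manifest.json.
#' @return A list bundle with elements prep, diversity, cohesion, ncm,
#'   core, structure, stability, path, manifest.
#' @export
runPipeline <- function(counts, meta, tree = NULL,
                        config = pipelineConfig(), outDir = NULL) {
  stopIfNot(inherits(config, "PipelineConfig"),
            "config must come from pipelineConfig()")
  cfg <- config
  seedOf <- function(stage) stageSeed(cfg$seed, stage)
  bundle <- list(config = cfg)

  ## ---- prep ----
  prep <- .stage("prep", {
    meta0 <- alignMeta(counts, meta)
    pr <- prepCounts(counts, minReads = cfg$minReads, depth = cfg$depth,
                     seed = seedOf("prep"), exclude = cfg$exclude)
    pr$meta <- alignMeta(pr$counts, meta0)
    pr$rel <- suppressWarnings(toRelative(pr$counts))
    pr
  })
  bundle$prep <- prep
  tab <- prep$counts; rel <- prep$rel; meta <- prep$meta
  hostIdx <- meta$habitat == cfg$host

  ## ---- diversity ----
  bundle$diversity <- .stage("diversity", {
    if (cfg$computeNRI && is.null(tree))
      stop("NRI requested but no tree supplied")
    prof <- diversityProfile(tab, tree = if (cfg$computeNRI) tree else NULL,
                             nNull = cfg$nriReps, seed = seedOf("diversity"))
    tests <- lapply(setdiff(names(prof), "sample_id"), function(metric)
      habitatEffectTest(prof[[metric]], meta))
    names(tests) <- setdiff(names(prof), "sample_id")
    list(profile = prof, habitat_tests = tests)
  })

  ## ---- cohesion / network ----
  bundle$cohesion <- .stage("cohesion_network", {
    conn <- connectedness(rel, nullReps = cfg$nullReps,
                          seed = seedOf("connectedness"))
    coh <- cohesion(rel, conn)
    ast <- suppressMessages(associationStrength(coh))
    corr <- spearmanMatrix(rel)
    net <- buildNetwork(corr, rThreshold = cfg$rThreshold,
                        pThreshold = cfg$pThreshold,
                        nSamples = nSamples(rel))
    rob <- networkRobustness(net, nOrders = cfg$robustnessOrders,
                             seed = seedOf("robustness"))
    list(connectedness = conn, cohesion = coh, association = ast,
         network = net, robustness = rob)
  })

  ## ---- neutral model per habitat ----
  bundle$ncm <- .stage("neutral_model", {
    fits <- lapply(HABITATS, function(h) {
      sub <- tab[meta$habitat == h, ]
      sub <- sub[, colSums(abundances(sub)) > 0]
      fitNCM(sub, N = prep$depth)
    })
    names(fits) <- HABITATS
    summaryTab <- do.call(rbind, lapply(HABITATS, function(h)
      cbind(habitat = h, ncmSummary(fits[[h]]))))
    list(fits = fits, summary = summaryTab)
  })

  ## ---- core stratification ----
  bundle$core <- .stage("core_partition", {
    overlap <- suppressWarnings(habitatOverlap(tab, meta))
    core <- detectCore(tab, meta, host = cfg$host, minRA = cfg$minRA,
                       minPrev = cfg$minPrev)
    cls <- classifyCore(tab, meta, core = core, host = cfg$host,
                        alpha = cfg$alpha)
    ga <- lapply(c("total-core", "SU+ES", "EC"), function(gp)
      groupAbundance(tab, cls, gp))
    names(ga) <- c("total-core", "SU+ES", "EC")
    list(overlap = overlap, detection = core, classification = cls,
         group_abundance = ga, shares = coreGroupShares(tab, cls))
  })
  cls <- bundle$core$classification

  ## ---- community structure ----
  bundle$structure <- .stage("community_structure", {
    dFull <- brayCurtis(rel)
    ord <- nmds(dFull, k = 2, nRestarts = cfg$nmdsRestarts,
                seed = seedOf("nmds"))
    perma <- permanova(dFull, meta$habitat, nPerms = cfg$nPerms,
                       seed = seedOf("permanova"))
    pw <- pairwisePermanova(dFull, meta$habitat, nPerms = cfg$nPerms,
                            seed = seedOf("pairwise_permanova"))
    disp <- betaDispersion(dFull, meta$habitat)
    cd <- do.call(rbind, lapply(setdiff(HABITATS, cfg$host), function(h)
      data.frame(pair = paste(cfg$host, h, sep = " vs "),
                 cdis = centroidDistance(dFull, meta$habitat,
                                         c(cfg$host, h)))))
    covTerms <- intersect(c("pH", "elevation"), names(meta))
    permaCov <- if (length(covTerms))
      permanovaTerms(dFull, meta, c(covTerms, "habitat"),
                     nPerms = cfg$nPerms, seed = seedOf("permanova_cov"))
    else NULL

    ## core subsets within host samples: Mantel vs the full community
    hostRel <- abundances(rel)[hostIdx, , drop = FALSE]
    dHost <- vegan::vegdist(hostRel, method = "bray")
    tx <- cls@taxa
    subsets <- list("total-core" = tx$taxon[tx$is_core],
                    "SU+ES" = tx$taxon[tx$label %in% c("SU", "ES")],
                    "EC" = tx$taxon[tx$label == "EC"])
    mant <- do.call(rbind, lapply(names(subsets), function(nm) {
      mem <- subsets[[nm]]
      if (length(mem) < 2)
        return(data.frame(subset = nm, r = NA, p = NA, n_perms = cfg$nPerms))
      sub <- hostRel[, mem, drop = FALSE]
      if (any(rowSums(sub) == 0))
        return(data.frame(subset = nm, r = NA, p = NA, n_perms = cfg$nPerms))
      dSub <- vegan::vegdist(sub, method = "bray")
      cbind(subset = nm,
            mantelTest(dHost, dSub, nPerms = cfg$nPerms,
                       seed = seedOf(paste0("mantel_", nm))))
    }))
    list(dist = dFull, nmds = ord, permanova = perma,
         pairwise_permanova = pw, dispersion = disp,
         centroid_distances = cd, permanova_covariates = permaCov,
         mantel_core = mant)
  })

  ## ---- stability ----
  bundle$stability <- .stage("stability", {
    avdAll <- do.call(rbind, lapply(HABITATS, function(h) {
      ids <- meta$sample_id[meta$habitat == h]
      cbind(habitat = h, avd(rel, sampleSet = ids))
    }))
    ast <- bundle$cohesion$association
    groupings <- c("total-core", "SU+ES", "EC")
    hostIds <- meta$sample_id[hostIdx]
    reg <- list()
    for (gp in groupings) {
      ab <- bundle$core$group_abundance[[gp]]
      x <- ab$abundance[match(hostIds, ab$sample_id)]
      yA <- avdAll$avd[match(hostIds, avdAll$sample_id)]
      yS <- ast$association_strength[match(hostIds, ast$sample_id)]
      reg[[paste0(gp, "_avd")]] <-
        tryCatch(stabilityRegression(x, yA), error = function(e) NULL)
      reg[[paste0(gp, "_association")]] <-
        tryCatch(stabilityRegression(x, yS), error = function(e) NULL)
    }
    hostTab <- rel[hostIdx, ]
    hostTab <- hostTab[, colSums(abundances(hostTab)) > 0]
    reps <- robustnessReplicates(hostTab, nBoot = cfg$nBootRobustness,
                                 rThreshold = cfg$rThreshold,
                                 pThreshold = cfg$pThreshold,
                                 seed = seedOf("robustness_boot"))
    idxList <- attr(reps, "samples")
    for (gp in groupings) {
      ab <- bundle$core$group_abundance[[gp]]
      xHost <- ab$abundance[match(hostIds, ab$sample_id)]
      xRep <- vapply(idxList, function(ix) mean(xHost[ix]), numeric(1))
      reg[[paste0(gp, "_robustness")]] <-
        tryCatch(stabilityRegression(xRep, reps$robustness),
                 error = function(e) NULL)
    }
    list(avd = avdAll, regressions = reg, robustness_replicates = reps)
  })

  ## ---- path models ----
  bundle$path <- .stage("path_model", {
    if (!cfg$computeNRI || !all(c("pH", "elevation") %in% names(meta)))
      return(NULL)
    prof <- bundle$diversity$profile
    hostMeta <- meta[hostIdx, ]
    semDat <- data.frame(pH = hostMeta$pH, elevation = hostMeta$elevation)
    for (h in setdiff(HABITATS, cfg$host)) {
      sib <- meta$sample_id[meta$habitat == h][match(hostMeta$plot,
                            meta$plot[meta$habitat == h])]
      semDat[[paste0(h, "_nri")]] <- prof$nri[match(sib, prof$sample_id)]
    }
    ordPts <- bundle$structure$nmds$points
    semDat$structure <- ordPts[match(hostMeta$sample_id,
                                     rownames(ordPts)), 1]
    if ("pathway_carbon_energy" %in% names(meta))
      semDat$pathway <- hostMeta$pathway_carbon_energy
    fits <- list()
    for (gp in c("total-core", "SU+ES", "EC")) {
      ab <- bundle$core$group_abundance[[gp]]
      semDat$core <- ab$abundance[match(hostMeta$sample_id, ab$sample_id)]
      edges <- rbind(
        data.frame(from = c("pH", "elevation", "litter_nri", "soil_nri"),
                   to = "core"),
        data.frame(from = "core", to = "structure"))
      if ("pathway" %in% names(semDat))
        edges <- rbind(edges,
                       data.frame(from = c("structure", "pH", "elevation"),
                                  to = "pathway"))
      edges <- edges[edges$from %in% names(semDat), ]
      ok <- all(vapply(unique(c(edges$from, edges$to)),
                       function(v) sd(semDat[[v]]) > 0, logical(1)))
      fits[[gp]] <- if (ok && complete.cases(semDat) |> all())
        tryCatch(fitPaths(pathModelSpec(edges$from, edges$to), semDat),
                 error = function(e) NULL)
      else NULL
    }
    list(data = semDat, fits = fits)
  })

  ## ---- manifest / outputs ----
  bundle$manifest <- .stage("manifest", {
    man <- list(
      package = "phyllocore",
      version = as.character(packageVersion("phyllocore")),
      config = cfg[setdiff(names(cfg), "exclude")],
      stage_seeds = vapply(c("prep", "diversity", "connectedness",
                             "robustness", "nmds", "permanova",
                             "pairwise_permanova", "permanova_cov",
                             "robustness_boot"),
                           seedOf, numeric(1)),
      n_samples = nSamples(tab), n_taxa = nTaxa(tab),
      depth = prep$depth,
      core_counts = as.list(table(cls@taxa$label)),
      ncm = bundle$ncm$summary[, c("habitat", "m", "r2")])
    man
  })

  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

#' Write a pipeline bundle to a directory
#'
#' Writes the main per-module TSV outputs and a manifest.json that
#' includes an md5 checksum of every written file. The manifest is
#' byte-identical across reruns with the same inputs and config.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(outDir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character()
  files <- c(files, wt(bundle$diversity$profile, "diversity_profile.tsv"))
  files <- c(files, wt(bundle$cohesion$cohesion, "cohesion.tsv"))
  files <- c(files, wt(bundle$cohesion$connectedness, "connectedness.tsv"))
  files <- c(files, wt(bundle$ncm$summary, "ncm_summary.tsv"))
  files <- c(files, wt(bundle$core$classification@taxa,
                       "core_classification.tsv"))
  files <- c(files, wt(bundle$core$shares, "core_group_shares.tsv"))
  ordDf <- data.frame(sample_id = rownames(bundle$structure$nmds$points),
                      bundle$structure$nmds$points,
                      stress = bundle$structure$nmds$stress)
  names(ordDf)[2:3] <- c("axis1", "axis2")
  files <- c(files, wt(ordDf, "nmds.tsv"))
  files <- c(files, wt(bundle$structure$pairwise_permanova,
                       "pairwise_permanova.tsv"))
  files <- c(files, wt(bundle$structure$mantel_core, "mantel_core.tsv"))
  files <- c(files, wt(bundle$stability$avd, "avd.tsv"))
  regs <- bundle$stability$regressions
  regDf <- do.call(rbind, lapply(names(regs), function(nm)
    if (!is.null(regs[[nm]])) cbind(model = nm, regs[[nm]]) else NULL))
  if (!is.null(regDf)) files <- c(files, wt(regDf, "stability_regressions.tsv"))
  edgePath <- file.path(outDir, "network_edges.tsv")
  writeEdgeList(bundle$cohesion$network, edgePath)
  files <- c(files, edgePath)

  man <- bundle$manifest
  sums <- tools::md5sum(sort(files))
  man$files <- lapply(seq_along(sums), function(i)
    list(file = basename(names(sums)[i]), md5 = unname(sums[i])))
  manPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(man, manPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manPath)
}
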