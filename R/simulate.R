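#' Scenario for the stratified litter-moss-soil simulator
#'
#' Bundles the design and effect sizes of a synthetic vertically
#' stratified system: by default 5 sites x 5 plots x 3 habitats (75
#' samples) with a host habitat ("sphagnum") harbouring planted
#' host-unique (SU), host-enriched (ES) and environmental-core (EC) taxa
#' on top of habitat specialists and background generalists.
#'
#' Abundances follow a log-normal law: each taxon has a base log-mean
#' drawn per class, habitat multipliers act multiplicatively on that mean
#' (ES taxa are \code{enrichmentFold} times more abundant in the host
#' habitat than elsewhere; SU and specialist taxa have multiplier zero
#' outside their habitat), covariate effects act on the log scale, and
#' structural zeros are then inserted per taxon-sample with a
#' class-specific probability, so the downstream zero-inflated beta model
#' is correctly specified. Counts are Poisson draws of the resulting
#' expectations.
#'
#' @param nSites number of sites (default 5).
#' @param nPlotsPerSite plots per site (default 5).
#' @param host host habitat, one of litter/sphagnum/soil.
#' @param nSU,nES,nEC,nSpecialist,nBackground taxa per class. Specialists
#'   are split between the two non-host habitats.
#' @param enrichmentFold ES host vs elsewhere abundance ratio (> 1).
#' @param zeroInflation named numeric, structural-zero probability per
#'   class (SU, ES, EC, specialist, background), each in [0, 1].
#' @param baseLogMean named numeric, log of the expected per-sample count
#'   of a taxon of each class in its favoured habitat.
#' @param taxonSdLog between-taxon sd of the base log-mean.
#' @param noiseSdLog per taxon-sample log-normal noise sd.
#' @param covariateEffects list with elements \code{pH_EC} (effect of
#'   standardised pH on EC log-abundance) and \code{elev_host} (effect of
#'   standardised elevation on SU/ES log-abundance).
#' @param seed integer seed.
#' @return A list of class "StratifiedScenario".
#' @export
stratifiedScenario <- function(nSites = 5, nPlotsPerSite = 5,
                               host = "sphagnum",
                               nSU = 20, nES = 20, nEC = 20,
                               nSpecialist = 40, nBackground = 100,
                               enrichmentFold = 5,
                               zeroInflation = c(SU = 0.05, ES = 0.05,
                                                 EC = 0.05, specialist = 0.2,
                                                 background = 0.5),
                               baseLogMean = c(SU = log(30), ES = log(40),
                                               EC = log(25),
                                               specialist = log(30),
                                               background = log(5)),
                               taxonSdLog = 0.4, noiseSdLog = 0.6,
                               covariateEffects = list(pH_EC = 0.5,
                                                       elev_host = -0.5),
                               seed = 1) {
  stopIfNot(host %in% HABITATS, "host must be litter, sphagnum or soil")
  stopIfNot(enrichmentFold > 1, "enrichmentFold must be > 1")
  stopIfNot(all(zeroInflation >= 0 & zeroInflation <= 1),
            "zeroInflation probabilities must lie in [0, 1]")
  stopIfNot(all(c(nSites, nPlotsPerSite) >= 1), "design counts must be >= 1")
  structure(as.list(environment()), class = "StratifiedScenario")
}

#' Simulate a vertically stratified microbial system with ground truth
#'
#' Generates a counts table over \code{nSites x nPlotsPerSite x 3
#' habitats} samples, a metadata table with pH and elevation covariates,
#' and per-taxon ground-truth class labels. SU taxa have zero counts
#' outside the host habitat by construction; ES taxa have an expected
#' host abundance \code{enrichmentFold} times their abundance elsewhere;
#' EC taxa have habitat-independent expectation. A per-sample proxy for a
#' predicted metabolic pathway abundance is included in the metadata with
#' a known linear dependence on the covariates and the host-specific
#' share, for exercising the path models.
#'
#' @param scn a \code{\link{stratifiedScenario}}.
#' @return A list with \code{counts} (\linkS4class{AbundanceTable}),
#'   \code{meta} (data.frame: sample_id, habitat, site, plot, pH,
#'   elevation, pathway_carbon_energy) and \code{truth} (list with
#'   \code{taxa} label frame and the generating \code{coefficients}).
#' @examples
#' sim <- simulateStratifiedSystem(stratifiedScenario(seed = 7))
#' sim$counts
#' table(sim$truth$taxa$class)
#' @export
simulateStratifiedSystem <- function(scn = stratifiedScenario()) {
  stopIfNot(inherits(scn, "StratifiedScenario"),
            "scn must come from stratifiedScenario()")
  withSeed(scn$seed, {
    habitats <- HABITATS
    others <- setdiff(habitats, scn$host)
    design <- expand.grid(habitat = habitats,
                          plot = seq_len(scn$nPlotsPerSite),
                          site = seq_len(scn$nSites),
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("S%dP%d_%s", design$site, design$plot,
                                design$habitat)
    nS <- nrow(design)

    ## covariates: elevation per site, pH per colony with habitat offsets
    elevSite <- sort(runif(scn$nSites, 1000, 1900))
    design$elevation <- elevSite[design$site]
    phHab <- c(litter = 4.8, sphagnum = 4.2, soil = 5.0)
    design$pH <- phHab[design$habitat] +
      rnorm(nS, 0, 0.25) - 0.0003 * (design$elevation - mean(elevSite))
    design$pH <- pmin(pmax(design$pH, 3), 8)

    ## taxon classes and per-class habitat multipliers
    classes <- c(rep("SU", scn$nSU), rep("ES", scn$nES), rep("EC", scn$nEC),
                 rep("specialist", scn$nSpecialist),
                 rep("background", scn$nBackground))
    K <- length(classes)
    taxa <- sprintf("ASV%04d", seq_len(K))
    specHab <- rep(others, length.out = scn$nSpecialist)
    baseLog <- scn$baseLogMean[classes] + rnorm(K, 0, scn$taxonSdLog)

    ## habitat multiplier matrix (taxa x habitats), on the mean scale
    mult <- matrix(1, K, length(habitats), dimnames = list(taxa, habitats))
    mult[classes == "SU", others] <- 0
    mult[classes == "ES", others] <- 1 / scn$enrichmentFold
    isSpec <- classes == "specialist"
    mult[isSpec, ] <- 0
    mult[cbind(which(isSpec), match(specHab, habitats))] <- 1
    ## background generalists get mild random habitat preferences
    nBg <- sum(classes == "background")
    if (nBg)
      mult[classes == "background", ] <-
        exp(matrix(rnorm(nBg * length(habitats), 0, 0.5), nBg))

    zPH <- as.numeric(scale(design$pH))
    zEl <- as.numeric(scale(design$elevation))
    bPH <- scn$covariateEffects$pH_EC
    bEl <- scn$covariateEffects$elev_host

    ## expected counts: lognormal mean x habitat multiplier x covariate term
    lam <- matrix(0, nS, K, dimnames = list(design$sample_id, taxa))
    habIdx <- match(design$habitat, habitats)
    for (i in seq_len(nS)) {
      covLog <- numeric(K)
      covLog[classes == "EC"] <- bPH * zPH[i]
      covLog[classes %in% c("SU", "ES")] <- bEl * zEl[i]
      lam[i, ] <- exp(baseLog + covLog +
                        rnorm(K, 0, scn$noiseSdLog)) * mult[, habIdx[i]]
    }

    ## structural zeros per taxon-sample, then Poisson counts
    ziProb <- scn$zeroInflation[classes]
    zi <- matrix(rbinom(nS * K, 1, rep(ziProb, each = nS)), nS, K)
    counts <- matrix(rpois(nS * K, lam * (1 - zi)), nS, K,
                     dimnames = dimnames(lam))

    hostMask <- design$habitat == scn$host
    hostShare <- rowSums(lam[, classes %in% c("SU", "ES"), drop = FALSE]) /
      pmax(rowSums(lam), 1e-12)
    truthCoef <- c(pathway_pH = -0.3, pathway_elev = -0.4,
                   pathway_hostShare = 0.5)
    design$pathway_carbon_energy <-
      truthCoef["pathway_pH"] * zPH + truthCoef["pathway_elev"] * zEl +
      truthCoef["pathway_hostShare"] * as.numeric(scale(hostShare)) +
      rnorm(nS, 0, 0.5)

    truthTaxa <- data.frame(
      taxon = taxa,
      class = ifelse(classes %in% c("SU", "ES", "EC"), classes, "other"),
      generator_class = classes,
      stringsAsFactors = FALSE)

    meta <- design[, c("sample_id", "habitat", "site", "plot", "pH",
                       "elevation", "pathway_carbon_energy")]
    meta$site <- paste0("site", meta$site)
    meta$plot <- sprintf("site%d_plot%d", design$site, design$plot)
    rownames(meta) <- NULL

    list(counts = AbundanceTable(counts, mode = "counts"),
         meta = meta,
         truth = list(taxa = truthTaxa, coefficients = truthCoef,
                      scenario = scn, host_mask = hostMask))
  })
}

#' Simulate neutral local communities (Moran model with immigration)
#'
#' Evolves \code{nCommunities} local communities of fixed size
#' \code{communitySize} from a shared source pool: at each replacement
#' event a uniformly chosen individual dies and is replaced, with
#' probability \code{migrationM}, by an immigrant drawn from the source
#' pool, otherwise by the offspring of a random local individual. This is
#' the process whose stationary per-taxon frequencies follow the beta
#' distribution underlying Sloan's neutral community model, so its output
#' is neutral by construction.
#'
#' @param sourcePool numeric vector of source relative abundances
#'   (normalised to sum to 1; must be non-negative).
#' @param nCommunities number of local communities (samples).
#' @param communitySize individuals per community (N).
#' @param migrationM immigration probability per replacement, in (0, 1].
#' @param generations number of single-individual replacement events per
#'   community. Equilibration of the per-taxon frequency distribution
#'   takes on the order of \code{communitySize / migrationM} events.
#' @param seed integer seed.
#' @return A counts-mode \linkS4class{AbundanceTable}
#'   (communities x taxa).
#' @export
simulateNeutralCommunities <- function(sourcePool, nCommunities,
                                       communitySize, migrationM,
                                       generations, seed) {
  stopIfNot(communitySize >= 1, "communitySize must be positive")
  stopIfNot(migrationM > 0 && migrationM <= 1,
            "migrationM must lie in (0, 1]")
  stopIfNot(all(sourcePool >= 0) && sum(sourcePool) > 0,
            "sourcePool must be non-negative with positive mass")
  pool <- sourcePool / sum(sourcePool)
  K <- length(pool)
  N <- as.integer(communitySize)
  E <- as.integer(generations)
  withSeed(seed, {
    out <- matrix(0L, nCommunities, K,
                  dimnames = list(sprintf("community_%03d",
                                          seq_len(nCommunities)),
                                  if (!is.null(names(pool))) names(pool)
                                  else sprintf("taxon_%04d", seq_len(K))))
    for (cc in seq_len(nCommunities)) {
      comm <- sample.int(K, N, replace = TRUE, prob = pool)
      if (E > 0) {
        death <- sample.int(N, E, replace = TRUE)
        birth <- sample.int(N, E, replace = TRUE)
        fromPool <- runif(E) < migrationM
        poolDraw <- sample.int(K, E, replace = TRUE, prob = pool)
        for (t in seq_len(E)) {
          comm[death[t]] <- if (fromPool[t]) poolDraw[t]
                            else comm[birth[t]]
        }
      }
      out[cc, ] <- tabulate(comm, nbins = K)
    }
    AbundanceTable(out, mode = "counts")
  })
}

#' Simulate a rooted pure-birth tree over given taxa
#'
#' Yule (pure-birth) topology with branch lengths from the constant-rate
#' birth process, deterministic per seed.
#'
#' @param taxonIds character vector of at least 2 tip labels.
#' @param seed integer seed.
#' @return An \code{ape::phylo} rooted binary tree with the given tips.
#' @export
simulateTree <- function(taxonIds, seed) {
  stopIfNot(length(taxonIds) >= 2, "need at least 2 taxa for a tree")
  withSeed(seed, {
    tree <- ape::rphylo(length(taxonIds), birth = 1, death = 0)
    tree$tip.label <- taxonIds
    tree
  })
}

#' Simulate linear-Gaussian data from a path-model DAG
#'
#' Variables are generated in topological order: exogenous variables are
#' standard normal; each endogenous variable is the coefficient-weighted
#' sum of its parents plus \code{noiseSd} Gaussian noise.
#'
#' @param dag data.frame with columns \code{from}, \code{to} (edge list;
#'   must be acyclic).
#' @param n number of observations.
#' @param coefficients numeric vector of per-edge coefficients, aligned
#'   with the rows of \code{dag}.
#' @param noiseSd residual standard deviation for endogenous variables.
#' @param seed integer seed.
#' @return A data.frame with one column per variable.
#' @export
simulatePathData <- function(dag, n, coefficients, noiseSd = 1, seed = 1) {
  dag <- as.data.frame(dag)
  stopIfNot(all(c("from", "to") %in% names(dag)),
            "dag needs 'from' and 'to' columns")
  stopIfNot(length(coefficients) == nrow(dag),
            "one coefficient per edge is required")
  vars <- topoSort(dag)  # errors on cycles
  withSeed(seed, {
    out <- as.data.frame(setNames(rep(list(numeric(n)), length(vars)), vars))
    for (v in vars) {
      par <- dag[dag$to == v, , drop = FALSE]
      if (!nrow(par)) {
        out[[v]] <- rnorm(n)
      } else {
        mu <- rep(0, n)
        for (k in seq_len(nrow(par)))
          mu <- mu + coefficients[which(dag$from == par$from[k] &
                                          dag$to == v)] * out[[par$from[k]]]
        out[[v]] <- mu + if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
      }
    }
    out
  })
}

#' Write a paper-like synthetic fixture set to disk
#'
#' Generates the default stratified scenario plus a matching pure-birth
#' tree and writes counts.tsv, meta.tsv, tree.nwk and truth.tsv.
#'
#' @param dir output directory (created if needed).
#' @param scn scenario, default \code{stratifiedScenario(seed = seed)}.
#' @param seed master seed.
#' @return Invisibly, the list returned by
#'   \code{\link{simulateStratifiedSystem}} with a \code{tree} element.
#' @export
writeFixtures <- function(dir, scn = NULL, seed = 1) {
  if (is.null(scn)) scn <- stratifiedScenario(seed = seed)
  sim <- simulateStratifiedSystem(scn)
  sim$tree <- simulateTree(taxonIDs(sim$counts), seed = stageSeed(seed, "tree"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAbundanceTable(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write.table(sim$truth$taxa, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sim)
}
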