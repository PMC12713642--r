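test_that("habitat overlap categorises presence patterns", {
  meta <- smallMeta(nPerHab = 2)
  m <- matrix(0, 6, 3, dimnames = list(meta$sample_id, c("a", "b", "c")))
  m[meta$habitat == "soil", "a"] <- 5                 # soil only
  m[, "b"] <- 3                                        # everywhere
  ov <- suppressWarnings(habitatOverlap(AbundanceTable(m), meta))
  expect_equal(ov$category[ov$taxon == "a"], "soil only")
  expect_equal(ov$category[ov$taxon == "b"], "all three")
  expect_false("c" %in% ov$taxon)                      # absent -> excluded
  expect_warning(habitatOverlap(AbundanceTable(m), meta), "excluded")
})

test_that("core detection applies inclusive 0.1%/80% thresholds exactly", {
  ## 100 host samples of 1e5 reads; focal taxon: count 125 in 80 samples
  ## -> prevalence exactly 0.8, mean relative abundance exactly 0.001
  n <- 100; total <- 100000
  m <- matrix(0, n, 3, dimnames = list(paste0("h", 1:n), c("focal", "low",
                                                           "fill")))
  m[1:80, "focal"] <- 125
  m[1:79, "low"] <- 200                      # 79% prevalence
  m[, "fill"] <- total - rowSums(m)
  meta <- data.frame(sample_id = rownames(m), habitat = "sphagnum",
                     site = "s1", plot = rownames(m))
  res <- detectCore(AbundanceTable(m), meta, host = "sphagnum")
  expect_true(res$is_core[res$taxon == "focal"])
  expect_false(res$is_core[res$taxon == "low"])

  ## 0.099% mean abundance at full prevalence fails the abundance gate
  m2 <- m
  m2[, "low"] <- 99                             # 99/1e5 = 0.099%
  m2[, "fill"] <- total - rowSums(m2[, c("focal", "low")])
  res2 <- detectCore(AbundanceTable(m2), meta, host = "sphagnum")
  expect_false(res2$is_core[res2$taxon == "low"])

  ## monotone in both thresholds: tightening never adds core taxa
  resTight <- detectCore(AbundanceTable(m), meta, minRA = 0.002,
                         minPrev = 0.9)
  expect_true(all(res$is_core | !resTight$is_core))
})

test_that("core detection recovers every planted core taxon", {
  sim <- simulateStratifiedSystem(stratifiedScenario(seed = 7))
  core <- detectCore(sim$counts, sim$meta)
  planted <- sim$truth$taxa$taxon[sim$truth$taxa$class %in%
                                    c("SU", "ES", "EC")]
  expect_setequal(core$taxon[core$is_core], planted)
})

test_that("zero-inflated beta recovery is within three standard errors", {
  set.seed(2)
  g <- rep(c("sphagnum", "litter"), each = 50)
  delta <- 1.5
  mu <- plogis(qlogis(0.05) + (g == "sphagnum") * delta)
  y <- rbeta(100, mu * 30, (1 - mu) * 30)
  y[rbinom(100, 1, 0.1) == 1] <- 0
  fit <- fitZIB(y, g, ref = "sphagnum")
  ct <- zibContrasts(fit)
  expect_lt(abs(ct$estimate[1] - delta), 3 * ct$se[1])
  expect_lt(ct$p[1], 0.001)
})

test_that("degenerate zero-inflated fits are flagged, not fabricated", {
  g <- rep(c("sphagnum", "litter", "soil"), each = 5)
  expect_true(fitZIB(rep(0, 15), g)$degenerate)

  ## one group entirely zero: its mu contrast is unavailable
  y <- c(rbeta(5, 2, 20), rbeta(5, 2, 20), rep(0, 5))
  fit <- fitZIB(y, g, ref = "sphagnum")
  ct <- zibContrasts(fit)
  expect_true(is.na(ct$p_adj[ct$contrast == "sphagnum - soil"]))
})

test_that("Holm-adjusted contrast p-values never undercut unadjusted
           ones and mvn adjustment stays in [p, 2p]", {
  set.seed(9)
  g <- rep(c("sphagnum", "litter", "soil"), each = 20)
  y <- rbeta(60, 2, 30); y[rbinom(60, 1, 0.2) == 1] <- 0
  fit <- fitZIB(y, g, ref = "sphagnum")
  for (adj in c("mvn", "holm")) {
    ct <- zibContrasts(fit, adjust = adj)
    expect_true(all(ct$p_adj >= ct$p - 1e-9, na.rm = TRUE))
    expect_true(all(ct$p_adj <= pmin(2 * ct$p, 1) + 1e-9, na.rm = TRUE))
  }
})

test_that("core stratification recovers the planted SU/ES/EC labels and
           partitions the core", {
  sim <- simulateStratifiedSystem(stratifiedScenario(seed = 7))
  pr <- prepCounts(sim$counts, seed = 3)
  cls <- suppressWarnings(classifyCore(pr$counts, sim$meta))
  tx <- cls@taxa[cls@taxa$is_core, ]
  truth <- sim$truth$taxa$class[match(tx$taxon, sim$truth$taxa$taxon)]
  expect_gte(mean(truth == tx$label), 0.9)

  ## labels partition: SU/ES/EC/unresolved are mutually exclusive by row
  expect_true(all(tx$label %in% c("SU", "ES", "EC", "core-unresolved")))
  ## SU implies zero abundance outside the host habitat
  su <- tx$taxon[tx$label == "SU"]
  nonHost <- sim$meta$sample_id[sim$meta$habitat != "sphagnum"]
  expect_true(all(abundances(pr$counts)[nonHost, su] == 0))
})

test_that("group abundances and shares obey the partition identities", {
  sim <- simulateStratifiedSystem(stratifiedScenario(
    seed = 4, nSU = 3, nES = 3, nEC = 3, nSpecialist = 4, nBackground = 12,
    nSites = 2, nPlotsPerSite = 3))
  cls <- suppressWarnings(classifyCore(sim$counts, sim$meta))
  shares <- coreGroupShares(sim$counts, cls)
  expect_equal(sum(shares$share_of_core_count), 100)
  expect_equal(sum(shares$share_of_core_abundance), 100)

  gaTot <- groupAbundance(sim$counts, cls, "total-core")
  gaHost <- groupAbundance(sim$counts, cls, "SU+ES")
  gaEC <- groupAbundance(sim$counts, cls, "EC")
  ## the three strata tile the core (no unresolved in this fixture)
  if (!any(cls@taxa$label == "core-unresolved"))
    expect_equal(gaTot$abundance, gaHost$abundance + gaEC$abundance)

  ## hand-built oracle on a 5-taxon table
  m <- matrix(c(10, 20, 30, 20, 20,
                5, 5, 40, 30, 20), 2, 5, byrow = TRUE,
              dimnames = list(c("x", "y"), paste0("t", 1:5)))
  cls2 <- new("CoreClassification", host = "sphagnum", minRA = 0.001,
              minPrev = 0.8, alpha = 0.05,
              taxa = data.frame(taxon = paste0("t", 1:5),
                                is_core = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                label = c("SU", "ES", "EC", "non-core",
                                          "non-core"),
                                host_prevalence = 1, host_mean_ra = 0.1,
                                p_vs_litter = NA_real_,
                                p_vs_soil = NA_real_))
  ga <- groupAbundance(AbundanceTable(m), cls2, "SU+ES")
  expect_equal(ga$abundance, c((10 + 20) / 100, (5 + 5) / 100))
  expect_equal(groupAbundance(AbundanceTable(m), cls2, "EC")$abundance,
               c(30 / 100, 40 / 100))
})
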