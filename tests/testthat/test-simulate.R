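test_that("stratified simulator honours its design contract", {
  scn <- stratifiedScenario(seed = 11)
  sim <- simulateStratifiedSystem(scn)
  expect_equal(nSamples(sim$counts), scn$nSites * scn$nPlotsPerSite * 3)
  expect_equal(table(sim$meta$habitat)[["sphagnum"]], 25)

  ## class sizes conserved exactly in the ground truth
  expect_equal(as.numeric(table(sim$truth$taxa$class)[c("SU", "ES", "EC")]),
               c(scn$nSU, scn$nES, scn$nEC))

  ## SU taxa never occur outside the host habitat
  su <- sim$truth$taxa$taxon[sim$truth$taxa$class == "SU"]
  nonHost <- sim$meta$habitat != "sphagnum"
  expect_true(all(abundances(sim$counts)[nonHost, su] == 0))

  ## determinism
  sim2 <- simulateStratifiedSystem(stratifiedScenario(seed = 11))
  expect_identical(abundances(sim$counts), abundances(sim2$counts))
  expect_identical(sim$meta, sim2$meta)
})

test_that("with no zero inflation SU taxa reach full host prevalence", {
  scn <- stratifiedScenario(seed = 5, zeroInflation = c(SU = 0, ES = 0,
                            EC = 0, specialist = 0, background = 0),
                            enrichmentFold = 10)
  sim <- simulateStratifiedSystem(scn)
  su <- sim$truth$taxa$taxon[sim$truth$taxa$class == "SU"]
  host <- sim$meta$habitat == "sphagnum"
  prev <- colMeans(abundances(sim$counts)[host, su] > 0)
  expect_true(all(prev == 1))
  expect_true(all(abundances(sim$counts)[!host, su] == 0))
})

test_that("ES enrichment fold is recovered empirically across seeds", {
  ratios <- vapply(1:20, function(s) {
    sim <- simulateStratifiedSystem(stratifiedScenario(seed = s,
                                                       enrichmentFold = 5))
    v <- abundances(sim$counts)
    rel <- v / rowSums(v)
    es <- sim$truth$taxa$taxon[sim$truth$taxa$class == "ES"]
    host <- sim$meta$habitat == "sphagnum"
    mean(colMeans(rel[host, es])) / mean(colMeans(rel[!host, es]))
  }, numeric(1))
  expect_gt(mean(ratios), 5 * 0.7)
  expect_lt(mean(ratios), 5 * 1.3)
})

test_that("neutral simulator conserves community size and tracks the
           source pool at high migration", {
  set.seed(3)
  pool <- rlnorm(100, 0, 1.5); pool <- pool / sum(pool)
  nc <- simulateNeutralCommunities(pool, 50, 500, migrationM = 1,
                                   generations = 5000, seed = 2)
  v <- abundances(nc)
  expect_true(all(rowSums(v) == 500))
  freqs <- colMeans(v / 500)
  ## with m = 1 every replacement is an immigrant: frequencies match the
  ## pool up to multinomial sampling noise
  expect_lt(mean(abs(freqs - pool)), 3 * mean(sqrt(pool * (1 - pool) /
                                                   (500 * 50))))

  ## determinism
  nc2 <- simulateNeutralCommunities(pool, 50, 500, 1, 5000, seed = 2)
  expect_identical(v, abundances(nc2))
})

test_that("neutral communities drift to monodominance when migration
           vanishes", {
  pool <- rep(1 / 50, 50)
  nc <- simulateNeutralCommunities(pool, 20, 100, migrationM = 1e-4,
                                   generations = 5 * 100^2, seed = 8)
  maxShare <- apply(abundances(nc) / 100, 1, max)
  expect_gt(mean(maxShare), 0.9)
})

test_that("simulated trees are rooted binary trees over the taxa", {
  expect_error(simulateTree("one", seed = 1), "at least 2")
  t2 <- simulateTree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  tr <- simulateTree(paste0("t", 1:17), seed = 4)
  expect_equal(ape::Nnode(tr), 16)        # binary: n - 1 internal nodes
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulateTree(paste0("t", 1:17), seed = 4)))
})

test_that("path-data generator is linear-Gaussian in topological order", {
  dag <- pathModelSpec(c("X", "Y"), c("Y", "Z"))
  d0 <- simulatePathData(dag, 50, c(1, 1), noiseSd = 0, seed = 3)
  expect_equal(d0$Z, d0$X)   # noiseless unit chain passes X through

  d <- simulatePathData(pathModelSpec("X", "Y"), 2000, 0.8, noiseSd = 1,
                        seed = 5)
  fit <- summary(lm(Y ~ X, d))
  expect_lt(abs(coef(fit)["X", "Estimate"] - 0.8),
            3 * coef(fit)["X", "Std. Error"])

  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"))
  expect_error(simulatePathData(cyc, 10, c(1, 1), 1, 1), "cycle")
  expect_identical(d, simulatePathData(pathModelSpec("X", "Y"), 2000, 0.8,
                                       noiseSd = 1, seed = 5))
})

test_that("fixture writer produces a consistent file set", {
  dir <- withr::local_tempdir()
  sim <- writeFixtures(dir, scn = stratifiedScenario(
    seed = 3, nSU = 5, nES = 5, nEC = 5, nSpecialist = 6, nBackground = 20,
    nSites = 2, nPlotsPerSite = 2))
  expect_true(all(file.exists(file.path(dir, c("counts.tsv", "meta.tsv",
                                               "tree.nwk", "truth.tsv")))))
  back <- readAbundanceTable(file.path(dir, "counts.tsv"))
  expect_equal(abundances(back), abundances(sim$counts))
  tr <- readTree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, taxonIDs(sim$counts))
})
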