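test_that("richness and inverse Simpson follow their closed forms", {
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(5, 0, 2)), 2)
  expect_equal(richness(sample(c(5, 0, 2))), 2)

  expect_equal(inverseSimpson(c(7, 0, 0)), 1)
  expect_equal(inverseSimpson(rep(3, 4)), 4)
  expect_equal(inverseSimpson(c(3, 1)), 1.6)
  expect_error(inverseSimpson(c(0, 0)), "all-zero")

  ## maximised exactly at the uniform composition
  set.seed(1)
  for (k in c(3, 6, 10)) {
    skew <- runif(k); skew <- skew + max(skew)  # non-uniform
    expect_lt(inverseSimpson(skew), k)
    expect_equal(inverseSimpson(rep(1 / k, k)), k)
  }
})

test_that("Faith PD sums the spanning branches including the root path", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3):0;")
  expect_equal(faithPD(c(A = 1), tr), 3)                 # tip to root
  expect_equal(faithPD(c(A = 2, B = 1), tr), 4)          # cherry + stem
  expect_equal(faithPD(c(A = 1, B = 1, C = 1), tr), sum(tr$edge.length))
  expect_equal(faithPD(setNames(numeric(3), c("A", "B", "C")), tr), 0)
  expect_error(faithPD(c(A = 1, Z = 1), tr), "Z")
})

test_that("Faith PD is monotone and matches picante", {
  tr <- simulateTree(paste0("t", 1:20), seed = 6)
  set.seed(2)
  for (rep in 1:5) {
    pres <- sample(tr$tip.label, 6)
    pd1 <- faithPD(pres, tr)
    pd2 <- faithPD(c(pres, sample(setdiff(tr$tip.label, pres), 1)), tr)
    expect_gte(pd2, pd1)
    comm <- matrix(as.numeric(tr$tip.label %in% pres), 1,
                   dimnames = list("s", tr$tip.label))
    expect_equal(pd1, picante::pd(comm, tr, include.root = TRUE)$PD)
  }
})

test_that("NRI detects clustering, is null-centered, and rejects
           degenerate communities", {
  tr <- simulateTree(paste0("t", 1:30), seed = 9)
  ## the two tips of a cherry are maximally clustered
  coph <- ape::cophenetic.phylo(tr)
  pair <- which(coph == min(coph[coph > 0]), arr.ind = TRUE)[1, ]
  samp <- setNames(numeric(30), tr$tip.label)
  samp[rownames(coph)[pair]] <- 1
  expect_gt(nri(samp, tr, nNull = 199, seed = 2), 0)

  ## sign is invariant to uniform branch scaling
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7
  expect_gt(nri(samp, tr2, nNull = 199, seed = 2), 0)

  ## all tips present -> the shuffle null is degenerate
  expect_error(nri(setNames(rep(1, 30), tr$tip.label), tr, nNull = 99,
                   seed = 1), "degenerate")

  ## random communities centre near zero
  set.seed(7)
  z <- replicate(200, {
    s <- setNames(numeric(30), tr$tip.label)
    s[sample(tr$tip.label, 6)] <- 1
    nri(s, tr, nNull = 99, seed = sample.int(1e6, 1))
  })
  expect_lt(abs(mean(z)), 0.1)
})

test_that("habitat effect test reproduces Type I/II equivalence on a
           balanced design and handles degenerate input", {
  meta <- smallMeta(nPerHab = 6)
  meta$site <- rep(rep(c("s1", "s2"), each = 3), 3)
  set.seed(5)
  v <- rnorm(18) + (meta$habitat == "soil") * 1.2
  res <- habitatEffectTest(v, meta)

  ## balanced: Type II habitat SS equals Type I with habitat entered last
  fit <- lm(v ~ factor(meta$site) * factor(meta$habitat))
  t1 <- anova(lm(v ~ factor(meta$site) + factor(meta$habitat) +
                   factor(meta$site):factor(meta$habitat)))
  expect_equal(res$anova$F[res$anova$term == "habitat"],
               t1$`F value`[2], tolerance = 1e-8)

  ## all-equal values: F = 0, p = 1 everywhere
  flat <- habitatEffectTest(rep(1.5, 18), meta)
  expect_true(all(flat$anova$F == 0) && all(flat$anova$p == 1))
  expect_true(all(flat$contrasts$p_adj == 1))

  ## three pairwise habitat contrasts, adjusted
  expect_equal(nrow(res$contrasts), 3)
  expect_true(all(res$contrasts$p_adj >= 0 & res$contrasts$p_adj <= 1))
})

test_that("diversity profile assembles all per-sample metrics", {
  sim <- simulateStratifiedSystem(stratifiedScenario(
    seed = 2, nSU = 4, nES = 4, nEC = 4, nSpecialist = 4, nBackground = 14,
    nSites = 2, nPlotsPerSite = 2))
  tr <- simulateTree(taxonIDs(sim$counts), seed = 3)
  prof <- diversityProfile(sim$counts, tr, nNull = 99, seed = 1)
  expect_equal(nrow(prof), nSamples(sim$counts))
  expect_true(all(prof$richness <= nTaxa(sim$counts)))
  expect_true(all(prof$inverse_simpson <= prof$richness + 1e-9))
  expect_true(all(prof$faith_pd >= 0))
})
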