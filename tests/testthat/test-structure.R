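test_that("Bray-Curtis matches hand computations and its semi-metric
           properties", {
  m <- matrix(c(1, 1, 0,
                0, 1, 1,
                1, 1, 0,
                2, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  d <- as.matrix(brayCurtis(AbundanceTable(m)))
  expect_equal(d["s1", "s2"], 0.5)         # hand computation
  expect_equal(d["s1", "s3"], 0)           # identical samples
  expect_equal(d["s2", "s4"], 1)           # disjoint supports
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  mz <- rbind(m, s5 = 0, s6 = 0)
  expect_error(brayCurtis(AbundanceTable(mz)), "s5")
})

test_that("NMDS reaches near-zero stress on embeddable distances with a
           monotone stress trace", {
  set.seed(5)
  pts <- matrix(rnorm(18 * 2), 18, 2)
  res <- nmds(dist(pts), nRestarts = 5, seed = 2)
  expect_lt(res$stress, 0.01)
  for (tr in res$allTraces) expect_true(all(diff(tr) <= 1e-10))
  expect_equal(colMeans(res$points), c(0, 0), tolerance = 1e-8)
})

test_that("NMDS recovers the rank order of a square and agrees with
           vegan on stress", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  d <- dist(sq)
  res <- nmds(d, nRestarts = 10, seed = 3)
  dr <- dist(res$points)
  expect_equal(order(as.numeric(dr)), order(as.numeric(d) +
                                              1e-9 * as.numeric(dr)))

  set.seed(8)
  comm <- matrix(rlnorm(12 * 20), 12, 20,
                 dimnames = list(paste0("s", 1:12), paste0("t", 1:20)))
  db <- brayCurtis(AbundanceTable(comm))
  own <- nmds(db, nRestarts = 20, seed = 4)
  ref <- vegan::monoMDS(db, k = 2, model = "global")
  expect_lt(abs(own$stress - ref$stress), 0.05)
})

test_that("PERMANOVA matches the exact enumeration at n = 6 and respects
           its bounds", {
  set.seed(42)
  base <- rlnorm(8)
  m <- rbind(t(replicate(3, base * exp(rnorm(8, 0, 0.6)))),
             t(replicate(3, rev(base) * exp(rnorm(8, 0, 0.6)))))
  rownames(m) <- paste0("s", 1:6)
  tab <- AbundanceTable(m)
  d <- brayCurtis(tab)
  g <- rep(c("a", "b"), each = 3)
  res <- suppressMessages(permanova(d, g, nPerms = 9999, seed = 3))

  D <- as.matrix(d)
  Fs <- apply(combn(6, 3), 2, function(ix)
    permanovaF(D, ifelse(1:6 %in% ix, "a", "b")))
  pExact <- mean(Fs >= permanovaF(D, g) - 1e-12)
  expect_lt(abs(res$p - pExact), 0.02)
  expect_equal(res$F, permanovaF(D, g), tolerance = 1e-8)
  expect_gte(res$p, 1 / (9999 + 1))
})

test_that("PERMANOVA R2 is invariant to sample order and pairwise p-values
           are Holm-dominated", {
  set.seed(13)
  m <- matrix(rlnorm(18 * 10), 18, 10,
              dimnames = list(paste0("s", 1:18), paste0("t", 1:10)))
  g <- rep(c("a", "b", "c"), each = 6)
  tab <- AbundanceTable(m)
  d <- brayCurtis(tab)
  r1 <- permanova(d, g, nPerms = 199, seed = 5)
  perm <- sample(18)
  d2 <- as.dist(as.matrix(d)[perm, perm])
  r2 <- permanova(d2, g[perm], nPerms = 199, seed = 5)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-10)

  pw <- pairwisePermanova(d, g, nPerms = 199, seed = 6)
  expect_true(all(pw$p_adj >= pw$p - 1e-12))
  expect_equal(nrow(pw), 3)

  expect_error(permanova(d, c(rep("a", 17), "b"), 99, 1), "2 samples")
})

test_that("separated compositions reach the minimum attainable p", {
  set.seed(12)
  m <- matrix(0, 20, 6, dimnames = list(paste0("s", 1:20), paste0("t", 1:6)))
  m[1:10, 1:3] <- rlnorm(30) + 1
  m[11:20, 4:6] <- rlnorm(30) + 1
  d <- brayCurtis(AbundanceTable(m))
  res <- suppressMessages(permanova(d, rep(c("a", "b"), each = 10),
                                    nPerms = 999, seed = 2))
  expect_equal(res$p, 0.001)
})

test_that("beta dispersion scales with spread and is zero for coincident
           points", {
  ## Euclidean fixture: doubling within-group spread doubles Disp
  set.seed(7)
  base <- matrix(rnorm(10 * 2), 10, 2)
  g <- rep(c("a", "b"), each = 5)
  mk <- function(scale) {
    pts <- base
    pts[g == "b", ] <- pts[g == "b", ] * scale
    d <- dist(pts)
    attr(d, "Labels") <- paste0("s", 1:10)
    betaDispersion(d, g)
  }
  d1 <- mk(1); d2 <- mk(2)
  expect_equal(d2$groups$disp[d2$groups$group == "b"],
               2 * d1$groups$disp[d1$groups$group == "b"],
               tolerance = 1e-8)

  ## coincident samples: zero dispersion; group of two: equal distances
  pts <- rbind(matrix(1, 3, 2), matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE))
  d <- dist(pts); attr(d, "Labels") <- paste0("s", 1:5)
  bd <- betaDispersion(d, c("a", "a", "a", "b", "b"))
  expect_equal(bd$groups$disp[bd$groups$group == "a"], 0)
  db <- bd$samples$dist_to_centroid[bd$samples$group == "b"]
  expect_equal(db[1], db[2])
})

test_that("centroid distances recover planted geometry", {
  ## two point clouds displaced by exactly 3 in the plane
  set.seed(9)
  a <- matrix(rnorm(12, 0, 0.3), 6, 2)
  a <- scale(a, scale = FALSE)              # centroid at the origin
  b <- sweep(a, 2, c(3, 0), "+")
  d <- dist(rbind(a, b))
  g <- rep(c("a", "b"), each = 6)
  expect_equal(centroidDistance(d, g, c("a", "b")), 3, tolerance = 1e-8)

  ## identical groups coincide; result ignores sample order
  dd <- dist(rbind(a, a))
  expect_equal(centroidDistance(dd, g, c("a", "b")), 0, tolerance = 1e-8)
  perm <- sample(12)
  dp <- as.dist(as.matrix(d)[perm, perm])
  expect_equal(centroidDistance(dp, g[perm], c("a", "b")), 3,
               tolerance = 1e-8)
})

test_that("Mantel statistics match identity, affine invariance and the
           full enumeration at n = 6", {
  set.seed(4)
  pts <- matrix(rnorm(12), 6, 2)
  d1 <- dist(pts)
  expect_equal(mantelTest(d1, d1, nPerms = 99, seed = 1)$r, 1)
  expect_equal(mantelTest(d1, 2 * d1 + 1, nPerms = 99, seed = 1)$r, 1)

  d2 <- dist(matrix(rnorm(12), 6, 2))
  res <- suppressMessages(mantelTest(d1, d2, nPerms = 9999, seed = 2))
  l1 <- as.matrix(d1); l2 <- as.matrix(d2)
  robs <- cor(l1[lower.tri(l1)], l2[lower.tri(l2)])
  rs <- vapply(permuteAll(1:6), function(p) {
    mp <- l2[p, p]
    cor(l1[lower.tri(l1)], mp[lower.tri(mp)])
  }, numeric(1))
  expect_equal(res$r, robs)
  expect_lt(abs(res$p - mean(rs >= robs - 1e-12)), 0.02)

  d3 <- dist(matrix(rnorm(10), 5, 2))
  expect_error(mantelTest(d1, d3, 99, 1), "size")
})
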