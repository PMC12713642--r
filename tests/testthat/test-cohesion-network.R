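test_that("Spearman matrix handles ranks, ties and constant taxa", {
  ## rows sum to 1 by construction so the constant column survives
  ## normalisation: a increasing, b decreasing, c in rank order 1,3,2,4,
  ## d constant, f absorbs the remainder
  e <- c(0.02, 0.06, 0.04, 0.08)
  m <- cbind(a = c(0.10, 0.20, 0.30, 0.40), b = c(0.40, 0.30, 0.20, 0.10),
             c = e, d = rep(0.25, 4), f = 0.25 - e)
  rownames(m) <- paste0("s", 1:4)
  rel <- AbundanceTable(m, mode = "relative")
  rho <- spearmanMatrix(rel)
  expect_equal(unname(diag(rho)[1:3]), rep(1, 3))
  expect_equal(rho["a", "b"], -1)
  expect_equal(rho["a", "c"], 0.8)   # hand rank computation
  expect_true(all(is.na(rho["d", c("a", "b", "c")])))
  expect_error(spearmanMatrix(relTable(m[1:3, ] + 0.01)), "4 samples")
})

test_that("connectedness null-corrects correlations and recovers planted
           structure deterministically", {
  set.seed(10)
  n <- 40; K <- 20
  m <- matrix(rlnorm(n * K), n, K)
  base <- rlnorm(n, 0, 1)
  m[, 1] <- base * exp(rnorm(n, 0, 0.05))
  m[, 2] <- base * exp(rnorm(n, 0, 0.05))
  rel <- relTable(m)
  cn <- connectedness(rel, nullReps = 100, seed = 3)
  expect_setequal(cn$taxon[order(-cn$pos)][1:2], c("t1", "t2"))
  expect_true(all(cn$pos >= 0) && all(cn$neg <= 0))
  expect_identical(cn, connectedness(rel, nullReps = 100, seed = 3))
  expect_error(connectedness(rel, nullReps = 10), "20")
})

test_that("null-corrected correlations are centred at zero on shuffled
           data", {
  set.seed(11)
  ## many taxa keep the compositional-closure correlation negligible
  m <- matrix(rlnorm(200 * 40), 200, 40)
  rel <- relTable(m)
  cn <- connectedness(rel, nullReps = 100, seed = 5)
  ## per-taxon sum of the signed parts estimates the mean corrected
  ## correlation; it should be centred near zero
  expect_lt(abs(mean(cn$pos + cn$neg)), 0.05)
})

test_that("cohesion is the abundance-weighted dot product with
           connectedness, and is linear in it", {
  m <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.2, 0.6,
                0.1, 0.8, 0.1,
                0.4, 0.4, 0.2), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  rel <- AbundanceTable(m, mode = "relative")
  conn <- data.frame(taxon = paste0("t", 1:3),
                     pos = c(0.2, 0, 0.5), neg = c(-0.1, -0.3, 0))
  coh <- cohesion(rel, conn)
  expect_equal(coh$pos, as.numeric(m %*% conn$pos))   # manual oracle
  expect_equal(coh$neg, as.numeric(m %*% conn$neg))
  expect_equal(coh$pos[1], 0.5 * 0.2 + 0.2 * 0.5)

  ## zero connectedness -> zero cohesion
  conn0 <- transform(conn, pos = 0, neg = 0)
  expect_true(all(cohesion(rel, conn0)$pos == 0))

  ## scaling one sign scales that sign's cohesion in every sample
  conn3 <- transform(conn, pos = pos * 3)
  expect_equal(cohesion(rel, conn3)$pos, coh$pos * 3)
  expect_equal(cohesion(rel, conn3)$neg, coh$neg)
})

test_that("association strength is the pos/|neg| ratio with an undefined
           flag at zero negative cohesion", {
  coh <- data.frame(sample_id = c("a", "b", "c"),
                    pos = c(0.2, 0.3, 0.4), neg = c(-0.2, -0.1, 0))
  expect_message(ast <- associationStrength(coh), "undefined")
  expect_equal(ast$association_strength[1:2], c(1, 3))
  expect_true(is.na(ast$association_strength[3]) && ast$undefined[3])
})

test_that("network construction applies inclusive thresholds", {
  taxa <- paste0("t", 1:4)
  id <- diag(4); dimnames(id) <- list(taxa, taxa)
  expect_equal(nrow(buildNetwork(id, 0.6, 0.05, 20)@edges), 0)

  full <- matrix(1, 4, 4, dimnames = list(taxa, taxa))
  expect_equal(nrow(buildNetwork(full, 0.6, 0.05, 20)@edges), 6)  # k(k-1)/2

  ## |rho| exactly at the threshold is kept
  m <- id; m[1, 2] <- m[2, 1] <- 0.6
  net <- buildNetwork(m, rThreshold = 0.6, pThreshold = 0.05, nSamples = 30)
  expect_equal(nrow(net@edges), 1)
  expect_equal(net@edges$rho, 0.6)
  expect_error(buildNetwork(id, 0.6, 0.05, nSamples = 3), "4")
})

test_that("robustness matches the complete-graph closed form and bounds", {
  rK <- networkRobustness(igraph::make_full_graph(10), nOrders = 200,
                          gridStep = 0.05, seed = 4)
  expect_lt(abs(rK$robustness - 0.5), 0.03)
  ## curve non-increasing (exact for K10: pure removal loss)
  expect_true(all(diff(rK$lcc) <= 1e-9))

  ## upper bound: no graph beats the complete-graph curve
  for (g in list(igraph::make_ring(12), igraph::make_star(12,
                 mode = "undirected"),
                 igraph::sample_gnp(12, 0.3))) {
    r <- networkRobustness(g, nOrders = 50, gridStep = 0.1, seed = 2)
    expect_lte(r$robustness, 0.5 + 1 / (2 * igraph::vcount(g)) + 0.02)
  }

  ## edgeless graph: near-zero robustness
  r0 <- networkRobustness(igraph::make_empty_graph(20, directed = FALSE),
                          nOrders = 20, gridStep = 0.1, seed = 1)
  expect_lt(r0$robustness, 0.1)
})
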