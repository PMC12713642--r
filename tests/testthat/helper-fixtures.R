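## Shared fixtures, built in code.

tinyCounts <- function() {
  m <- matrix(c(5, 0, 2,
                3, 1, 0,
                0, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  AbundanceTable(m)
}

relTable <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  AbundanceTable(m / rowSums(m), mode = "relative")
}

## small metadata frame for a litter/sphagnum/soil design
smallMeta <- function(nPerHab = 5, nSites = 1) {
  hab <- rep(c("litter", "sphagnum", "soil"), each = nPerHab)
  data.frame(sample_id = paste0(hab, "_", rep(seq_len(nPerHab), 3)),
             habitat = hab,
             site = paste0("site", rep(rep(seq_len(nSites),
                                           length.out = nPerHab), 3)),
             plot = paste0("p", rep(seq_len(nPerHab), 3)),
             stringsAsFactors = FALSE)
}

## all permutations of a small vector (enumeration oracles)
permuteAll <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permuteAll(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

## PERMANOVA pseudo-F computed from first principles (Gower centering)
permanovaF <- function(D, g) {
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G)) + mean(G)
  H <- stats::model.matrix(~factor(g))
  H <- H %*% solve(crossprod(H)) %*% t(H)
  ssb <- sum(diag(H %*% G))
  sst <- sum(diag(G))
  a <- length(unique(g)) - 1
  (ssb / a) / ((sst - ssb) / (n - a - 1))
}
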