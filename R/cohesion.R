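#' Spearman correlation matrix among taxa
#'
#' Symmetric matrix of Spearman's rho (average-rank ties) across samples.
#' Taxa with zero variance across samples have undefined correlations;
#' their rows/columns are returned as NA and are excluded by downstream
#' steps.
#'
#' @param tab relative-mode \linkS4class{AbundanceTable} with >= 4 samples.
#' @return A taxa x taxa correlation matrix (diagonal 1; NA for
#'   constant taxa).
#' @export
spearmanMatrix <- function(tab) {
  assertRelative(tab, "spearmanMatrix")
  stopIfNot(nSamples(tab) >= 4, "need at least 4 samples")
  v <- abundances(tab)
  const <- apply(v, 2, function(x) var(x) == 0)
  rho <- suppressWarnings(cor(v, method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho)[!const] <- 1
  rho
}

#' Null-corrected taxon connectedness (Herren-McMahon)
#'
#' For every taxon, pairwise Spearman correlations with all other taxa
#' are corrected by subtracting the mean correlation obtained under a
#' taxa-shuffle null (each partner taxon's abundances independently
#' permuted across samples, \code{nullReps} times). Positive
#' connectedness is the mean of the corrected correlations that are
#' positive; negative connectedness the mean of those that are negative.
#' Constant taxa are excluded.
#'
#' @param tab relative-mode \linkS4class{AbundanceTable}.
#' @param nullReps number of shuffles (>= 20; default 200).
#' @param seed integer seed.
#' @return data.frame: taxon, pos (>= 0), neg (<= 0).
#' @export
connectedness <- function(tab, nullReps = 200, seed = 1) {
  assertRelative(tab, "connectedness")
  stopIfNot(nullReps >= 20, "nullReps below 20 gives too coarse a null")
  v <- abundances(tab)
  keep <- apply(v, 2, function(x) var(x) > 0)
  v <- v[, keep, drop = FALSE]
  K <- ncol(v)
  stopIfNot(K >= 2, "need at least 2 non-constant taxa")
  R <- apply(v, 2, rank)  # spearman = pearson on ranks
  obs <- cor(R)
  nullMean <- withSeed(seed, {
    acc <- matrix(0, K, K)
    n <- nrow(R)
    for (r in seq_len(nullReps)) {
      Rp <- apply(R, 2, sample, size = n)
      acc <- acc + cor(R, Rp)  # [i, j] = cor(x_i, permuted x_j)
    }
    acc / nullReps
  })
  corrected <- obs - nullMean
  diag(corrected) <- NA
  pos <- apply(corrected, 1, function(x) {
    x <- x[!is.na(x) & x > 0]; if (length(x)) mean(x) else 0 })
  neg <- apply(corrected, 1, function(x) {
    x <- x[!is.na(x) & x < 0]; if (length(x)) mean(x) else 0 })
  data.frame(taxon = colnames(v), pos = pos, neg = neg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample cohesion
#'
#' Positive cohesion of a sample is the sum over taxa of relative
#' abundance times positive connectedness; negative cohesion analogous.
#' These summarise the strength of cooperative vs competitive
#' associations each community participates in.
#'
#' @param tab relative-mode \linkS4class{AbundanceTable}.
#' @param conn connectedness frame from \code{\link{connectedness}},
#'   computed on the same taxa.
#' @return data.frame: sample_id, pos (>= 0), neg (<= 0).
#' @export
cohesion <- function(tab, conn) {
  assertRelative(tab, "cohesion")
  stopIfNot(all(conn$taxon %in% taxonIDs(tab)),
            "connectedness taxa not found in the table")
  v <- abundances(tab)[, conn$taxon, drop = FALSE]
  data.frame(sample_id = sampleIDs(tab),
             pos = as.numeric(v %*% conn$pos),
             neg = as.numeric(v %*% conn$neg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Species association strength
#'
#' Ratio of positive to absolute negative cohesion per sample. Samples
#' with zero negative cohesion get NA (flagged undefined, excluded from
#' regressions) rather than an error.
#'
#' @param coh cohesion frame from \code{\link{cohesion}}.
#' @return data.frame: sample_id, association_strength, undefined flag.
#' @export
associationStrength <- function(coh) {
  und <- coh$neg == 0
  out <- data.frame(sample_id = coh$sample_id,
                    association_strength = ifelse(und, NA_real_,
                                                  coh$pos / abs(coh$neg)),
                    undefined = und, stringsAsFactors = FALSE)
  if (any(und))
    message(sum(und), " sample(s) have zero negative cohesion; ",
            "association strength flagged undefined")
  out
}
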