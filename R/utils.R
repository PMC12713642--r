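## Internal helpers: seeded evaluation, seed derivation, input checks.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
## state afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic per-stage seed: master seed combined with a small string
## hash of the stage name, kept inside 32-bit integer range.
stageSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) + h) %% 2147483587L)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

assertCounts <- function(tab, what = "this operation") {
  stopIfNot(is(tab, "AbundanceTable"),
            "input must be an AbundanceTable")
  stopIfNot(abundanceMode(tab) == "counts",
            paste0(what, " requires a counts-mode AbundanceTable"))
  invisible(tab)
}

assertRelative <- function(tab, what = "this operation") {
  stopIfNot(is(tab, "AbundanceTable"),
            "input must be an AbundanceTable")
  stopIfNot(abundanceMode(tab) == "relative",
            paste0(what, " requires a relative-mode AbundanceTable"))
  invisible(tab)
}

## Align a metadata frame to a table's samples (order and identity).
alignMeta <- function(tab, meta) {
  stopIfNot(is.data.frame(meta) && "sample_id" %in% names(meta),
            "metadata must be a data.frame with a sample_id column")
  stopIfNot(!anyDuplicated(meta$sample_id),
            "metadata has duplicated sample_id rows")
  miss <- setdiff(sampleIDs(tab), meta$sample_id)
  stopIfNot(length(miss) == 0,
            paste0("samples missing from metadata: ",
                   paste(head(miss, 5), collapse = ", ")))
  meta[match(sampleIDs(tab), meta$sample_id), , drop = FALSE]
}

HABITATS <- c("litter", "sphagnum", "soil")
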