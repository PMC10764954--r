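#' @useDynLib cbctafn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a master seed (kept < 2^31).
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483587)
}

# Root-mean-square difference of two arrays over an optional mask.
rmse <- function(a, b, mask = NULL) {
  d <- as.numeric(a) - as.numeric(b)
  if (!is.null(mask)) d <- d[as.logical(mask)]
  sqrt(mean(d^2))
}
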