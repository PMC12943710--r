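#' @useDynLib rhizonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor cov dist lm median optimize p.adjust pbeta
#'   pnorm pt qbeta quantile rbinom reformulate rexp rlnorm rmultinom rnorm
#'   runif sd setNames var wilcox.test
#' @importFrom graphics lines
#' @importFrom utils read.table write.table combn
NULL

#' Derive a child seed from a master seed
#'
#' All randomized operations in the pipeline take a single integer seed;
#' independent stages derive their own sub-stream deterministically so that
#' changing one stage's settings never perturbs another stage's draws.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) + 1000003 * (offset + 1)) %% 2147483647)
}

## row minima of a numeric matrix via pmin over columns (fast, base-only)
row_mins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

## evaluate an expression under a local RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
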