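#' @importFrom stats approx cmdscale cor cutree dist hclust mad median
#'   p.adjust plogis pnorm pt qlogis quantile rbeta rbinom rchisq rlnorm
#'   rnorm runif sd setNames var as.dist
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib methylforge, .registration = TRUE
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Deterministic per-stage sub-seed
#'
#' Expands one master seed into distinct per-stage seeds (kept below 2^31)
#' so that every pipeline stage is independently reproducible.
#'
#' @param seed integer master seed.
#' @param stage one of `simulate`, `preprocess`, `dmp`, `dmr`, `cnv`,
#'   `train`, `evaluate`, `validate`.
#' @return an integer-valued seed.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, preprocess = 2L, dmp = 3L, dmr = 4L,
               cnv = 5L, train = 6L, evaluate = 7L, validate = 8L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

logit2 <- function(b) log2(b / (1 - b))

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(name, " must be in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
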