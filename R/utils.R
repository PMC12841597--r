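#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor median p.adjust pt qnorm quantile rnorm
#'   runif sd setNames wilcox.test binom.test phyper rpois lm resid
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a temporary RNG state so library code never
## clobbers the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Stable 31-bit string hash (polynomial rolling hash). Used to derive
## per-sample RNG substreams so that adding samples to a cohort never
## reshuffles the noise of existing ones.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

substream_seed <- function(base_seed, id) {
  as.integer((as.numeric(base_seed) + stable_hash(id)) %% 2147483647)
}

## Spearman rho of y against each column of X (ties -> average ranks).
## Constant columns yield NA.
spearman_vec <- function(X, y) {
  ry <- rank(y)
  RX <- apply(X, 2L, rank)
  if (is.null(dim(RX))) RX <- matrix(RX, ncol = ncol(X))
  suppressWarnings(drop(cor(RX, ry)))
}

## Two-sided p for a Spearman rho under the Student-t model on n-2 df.
spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho) & n > 2
  r <- pmin(pmax(rho[ok], -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
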