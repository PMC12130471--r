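#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.dist complete.cases cor cutree dist hclust
#'   kmeans median pchisq plogis prcomp qlogis qnorm quantile rbinom rexp
#'   rgamma rlnorm rmultinom runif sd setNames rnorm dnorm
#' @importFrom utils head read.csv read.delim write.csv packageVersion
#' @importFrom mclust Mclust mclustBIC
NULL

# Run code with a temporary RNG state; restores the caller's state afterwards.
# All stochastic operations in the package route through this so a single
# root seed yields bit-identical output regardless of ambient RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Stable substream seed for unit `index` under root `seed`.  A small
# multiplicative hash keeps substreams decorrelated while staying inside the
# 32-bit integer range R requires of set.seed().
substream_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647
  as.integer(s)
}

assert_prob_vector <- function(p, field, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("configuration error: '%s' must be a non-negative probability vector", field),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("configuration error: '%s' must sum to 1 (got %.12f)", field, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

assert_count <- function(x, field) {
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x)) {
    stop(sprintf("configuration error: '%s' must be a positive integer count", field),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Largest-remainder apportionment of n into round(n * p) integer counts that
# sum to n exactly.
apportion_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
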