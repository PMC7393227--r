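#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic seed splitting: every stochastic stage draws from its own
# stream derived from (master seed, stage label), so adding a stage never
# perturbs the draws of another. Result always in [1, 2^31 - 2].
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Run an expression under a fixed RNG state without touching the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# Matrix helper: counts/expression with genes in rows, samples in columns.
as_gene_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- x[[1]]
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    m
  } else {
    as.matrix(x)
  }
}
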