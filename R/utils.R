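#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test kmeans median quantile rnorm runif sd var
#' @importFrom utils head read.csv write.csv read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib crossmode, .registration = TRUE
NULL

# column standardization used throughout: parameters from `fit_rows` only,
# zero-variance columns get sd treated as 1 (standardized value 0 on fit rows)
.col_standardizer <- function(x, fit_rows) {
  xf <- x[fit_rows, , drop = FALSE]
  mu <- colMeans(xf)
  s <- sqrt(colSums(sweep(xf, 2L, mu)^2) / (nrow(xf) - 1L))
  s[!is.finite(s) | s <= 0] <- 1
  list(mean = mu, sd = s)
}

.apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2L, std$mean), 2L, std$sd, "/")
}

.assert_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  invisible(x)
}

# Pearson correlation that treats degenerate (constant) inputs as 0 rather
# than NA; used for per-voxel influence where masked data can be constant
.safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# add-one permutation p-value: never exactly zero
.perm_p <- function(null, observed) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# deterministic polynomial hash of a string, for config provenance stamps
.str_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# derive a child seed (< 2^31) from a master seed and a stage label
.child_seed <- function(seed, label) {
  s <- (as.numeric(seed) %% 2147483647)
  for (b in utf8ToInt(label)) s <- (s * 31 + b) %% 2147483629
  as.integer(s + 1)
}
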