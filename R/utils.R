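stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

msgf <- function(...) message(sprintf(...))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

assert_cols <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(x)
}

# columns that are constant up to floating-point noise (relative to their
# magnitude), e.g. a ratio of two proportional aggregates
constant_columns <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  !is.finite(sds) | sds <= 1e-10 * pmax(1, abs(colMeans(X)))
}

# column-wise standardization that keeps the centring/scaling vectors
standardize_matrix <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    stopf("zero-variance column(s): %s", paste(colnames(X)[zero], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(x = Xs, center = ctr, scale = scl)
}
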