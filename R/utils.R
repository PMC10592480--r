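# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Extract the strict upper triangle (diagonal excluded) of a square matrix as
## a vector, column-major. All map fits and map distances operate on this
## vector: the diagonal is identically 1 and carries no information.
upper_tri_vec <- function(m) {
  m[upper.tri(m, diag = FALSE)]
}

## Inverse of upper_tri_vec for a symmetric matrix with unit diagonal.
vec_to_corr_map <- function(v, n) {
  m <- diag(1, n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

## row-wise standardization (mean 0, sd 1); constant rows -> error or NA
standardize_rows <- function(x, na_ok = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  bad <- s <= 0
  if (any(bad) && !na_ok)
    stop("constant rows cannot be standardized (rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")", call. = FALSE)
  xc / ifelse(s > 0, s, NA_real_)
}

## Pearson correlation between corresponding rows of two matrices
rowwise_cor <- function(a, b) {
  az <- a - rowMeans(a)
  bz <- b - rowMeans(b)
  rowSums(az * bz) / sqrt(rowSums(az^2) * rowSums(bz^2))
}
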