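## rank-sum z and p for one pair of samples; z > 0 when group b is larger.
## Exact p by the Wilcoxon distribution when both groups are small and
## tie-free, otherwise the normal approximation with tie correction.
ranksum_entry <- function(a, b, exact_max_n = 10L) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  Ub <- sum(r[(na + 1):N]) - nb * (nb + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (Ub - mu) / sqrt(sig2) else 0
  has_ties <- any(ties > 1)
  if (na <= exact_max_n && nb <= exact_max_n && !has_ties) {
    p <- stats::pwilcox(min(Ub, na * nb - Ub), nb, na)
    p <- min(1, 2 * p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  c(z = z, p = p)
}

#' Entrywise rank-sum comparison of two groups of correlation maps
#'
#' For every unique (upper-triangle) map entry, a two-sided Wilcoxon
#' rank-sum test compares the two groups of maps; p-values are
#' Bonferroni-corrected over the number of unique entries tested. The
#' returned display z-map has z set to 0 for insignificant entries (the
#' raw z-map is retained). Sign convention: z > 0 where group b exceeds
#' group a.
#'
#' @param maps_a,maps_b ROI x ROI x n arrays (or lists of matrices), n >= 2
#'   per group.
#' @param alpha family-wise significance level (default 0.05).
#' @return object of class `map_comparison`: `z_map`, `p_map` (raw),
#'   `p_corrected`, `z_display` (zeroed where insignificant),
#'   `significant_mask`, `alpha`, `n_tests`, group sizes.
#' @export
ranksum_map_compare <- function(maps_a, maps_b, alpha = 0.05) {
  as_arr <- function(m) if (is.list(m)) simplify2array(m) else m
  a <- as_arr(maps_a); b <- as_arr(maps_b)
  if (length(dim(a)) != 3L || length(dim(b)) != 3L || dim(a)[3] < 2L || dim(b)[3] < 2L)
    stop("need at least 2 maps per group", call. = FALSE)
  p <- dim(a)[1]
  ut <- upper.tri(matrix(0, p, p))
  idx <- which(ut)
  n_tests <- length(idx)
  A <- apply(a, 3L, function(m) m[ut])
  B <- apply(b, 3L, function(m) m[ut])
  zs <- numeric(n_tests); ps <- numeric(n_tests)
  for (i in seq_len(n_tests)) {
    zp <- ranksum_entry(A[i, ], B[i, ])
    zs[i] <- zp["z"]; ps[i] <- zp["p"]
  }
  pc <- pmin(1, ps * n_tests)
  sig <- pc < alpha
  mk <- function(v, fill = 0) {
    m <- matrix(fill, p, p); m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  structure(list(z_map = mk(zs), p_map = mk(ps, fill = 1),
                 p_corrected = mk(pc, fill = 1),
                 z_display = mk(ifelse(sig, zs, 0)),
                 significant_mask = mk(sig, fill = FALSE) > 0,
                 alpha = alpha, n_tests = n_tests,
                 n_a = dim(a)[3], n_b = dim(b)[3]),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum map comparison: %d vs %d maps, %d entries tested\n",
              x$n_a, x$n_b, x$n_tests))
  cat(sprintf("  %d entries significant at alpha = %g (Bonferroni)\n",
              sum(x$significant_mask[upper.tri(x$significant_mask)]), x$alpha))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `k = sup |ECDF_x - ECDF_y|` evaluated at the pooled sample
#' points, with the asymptotic p-value of the Kolmogorov distribution.
#'
#' @param x,y nonempty numeric samples.
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts); Fy <- stats::ecdf(y)(pts)
  k <- max(abs(Fx - Fy))
  en <- sqrt(length(x) * length(y) / (length(x) + length(y)))
  lam <- (en + 0.12 + 0.11 / en) * k
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  list(statistic = k, p_value = max(0, min(1, p)))
}

#' Epanechnikov kernel density estimate
#'
#' Kernel \eqn{K(u) = 0.75 (1 - u^2)} on \eqn{|u| \le 1}. The default
#' bandwidth is Silverman's reference rule rescaled by the canonical
#' bandwidth ratio of the Epanechnikov kernel (factor 2.214 relative to
#' the Gaussian rule).
#'
#' @param samples numeric vector (>= 2 values).
#' @param bandwidth kernel half-width; default as described.
#' @param n_grid grid resolution.
#' @return list with `x` (grid), `y` (density), `bandwidth`.
#' @export
epanechnikov_kde <- function(samples, bandwidth = NULL, n_grid = 512L) {
  s <- samples[is.finite(samples)]
  if (length(s) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(s) == 0) {
    warning("zero-variance sample; density degenerates to a spike")
    bandwidth <- bandwidth %||% max(abs(s[1]) * 1e-3, 1e-3)
  }
  h <- bandwidth %||% (2.214 * stats::bw.nrd0(s))
  grid <- seq(min(s) - h, max(s) + h, length.out = n_grid)
  y <- vapply(grid, function(g) {
    u <- (g - s) / h
    mean(0.75 * pmax(1 - u^2, 0)) / h
  }, numeric(1))
  list(x = grid, y = y, bandwidth = h)
}

#' Compare groups of correlation coefficients on the Fisher z scale
#'
#' Applies the variance-stabilizing transform `atanh(r)` and compares the
#' groups by one-way ANOVA plus pairwise Welch t-tests.
#'
#' @param r_groups named list of numeric vectors of Pearson correlations
#'   (each |r| < 1; values at the boundary are clipped with a warning).
#' @return list with `F`, `p` (ANOVA), `pairwise` (matrix of pairwise
#'   t-test p-values), and `z_groups` (transformed data).
#' @export
fisher_z_compare <- function(r_groups) {
  if (is.null(names(r_groups)))
    names(r_groups) <- paste0("g", seq_along(r_groups))
  z <- lapply(r_groups, function(r) {
    if (any(abs(r) >= 1)) {
      warning("|r| = 1 clipped before the Fisher transform")
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    }
    atanh(r)
  })
  dat <- data.frame(z = unlist(z, use.names = FALSE),
                    g = factor(rep(names(z), lengths(z)), levels = names(z)))
  av <- stats::anova(stats::aov(z ~ g, data = dat))
  pw <- stats::pairwise.t.test(dat$z, dat$g, p.adjust.method = "none",
                               pool.sd = FALSE)$p.value
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1], pairwise = pw, z_groups = z)
}
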