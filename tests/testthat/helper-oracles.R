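# independent oracles used across tests

## projected-gradient solver for min ||Ax - b||^2 s.t. x >= 0
proj_grad_nnls <- function(A, b, iters = 50000L) {
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  step <- 1 / max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  x <- numeric(ncol(A))
  for (i in seq_len(iters)) {
    x_new <- pmax(0, x - step * (drop(AtA %*% x) - Atb))
    if (max(abs(x_new - x)) < 1e-14) { x <- x_new; break }
    x <- x_new
  }
  x
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## brute-force minimum assignment cost
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  costs <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(cost = min(costs), perm = unname(perms[which.min(costs), ]))
}

## adjusted Rand index (prefer mclust when available)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## same partition up to relabeling?
same_partition <- function(a, b) {
  isTRUE(all.equal(ari(a, b), 1))
}
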