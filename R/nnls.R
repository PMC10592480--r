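#' Non-negative least squares by the active-set (Lawson-Hanson) algorithm
#'
#' Solves \eqn{\min_{x \ge 0} \|Ax - b\|_2^2}. This primitive underlies both
#' the cluster-count evaluation (pixel traces regressed on centroid basis
#' sets) and the behavioral correlation-state decomposition (windowed
#' correlation maps regressed on state basis maps).
#'
#' The algorithm works entirely from the normal-equation cross-products, so
#' repeated solves against a fixed design (as in per-pixel or per-window
#' fitting) reuse `crossprod(A)`.
#'
#' @param A numeric matrix (m x n design).
#' @param b numeric vector (length m).
#' @param tol nonnegative tolerance used for optimality and feasibility
#'   checks, relative to the scale of `crossprod(A, b)`.
#' @return numeric vector of length `ncol(A)`, all entries `>= 0`.
#' @examples
#' A <- cbind(c(1, 0, 1), c(0, 1, 1))
#' nnls_solve(A, c(1, 2, 3))
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  nnls_from_cross(crossprod(A), drop(crossprod(A, b)), tol = tol)
}

## Lawson-Hanson on the normal equations: AtA (n x n), Atb (length n).
nnls_from_cross <- function(AtA, Atb, tol = 1e-10) {
  n <- length(Atb)
  x <- numeric(n)
  P <- logical(n)                       # passive (free) set
  scale <- max(abs(Atb), 1)
  maxit <- 50L * n
  it <- 0L
  repeat {
    w <- Atb - drop(AtA %*% x)          # negative gradient
    if (all(P) || max(w[!P]) <= tol * scale) break
    idx <- which(!P)
    P[idx[which.max(w[idx])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) { x <- s; break }
      Q <- P & (s <= tol)
      alpha <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + alpha * (s - x)
      P <- P & (x > tol)
      x[!P] <- 0
      it <- it + 1L
      if (it > maxit) break
    }
    it <- it + 1L
    if (it > maxit) break
  }
  pmax(x, 0)
}
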