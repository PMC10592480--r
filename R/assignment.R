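#' Solve the linear assignment problem
#'
#' Minimum-cost perfect matching between the rows and columns of a square
#' cost matrix (Hungarian method, shortest-augmenting-path formulation,
#' O(n^3)). Used to establish bilateral ROI pairs from centroid correlations
#' and to canonically relabel repeated parcellation maps before taking a
#' per-pixel mode.
#'
#' @param cost square numeric matrix; `cost[i, j]` is the cost of assigning
#'   row `i` to column `j`.
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @examples
#' solve_assignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("'cost' must be a square matrix", call. = FALSE)
  if (any(!is.finite(cost))) stop("'cost' must be finite", call. = FALSE)
  n <- nrow(cost)
  ## columns are indexed 1..n+1 with column 1 a virtual slot
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)                  # p[j]: row matched to column j-1
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in 2:(n + 1L)) if (p[j] > 0L) out[p[j]] <- j - 1L
  out
}
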