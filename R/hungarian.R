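# Dense O(n^3) Hungarian (Kuhn-Munkres with potentials) for the linear
# assignment problems used in association and metric evaluation. Written
# against a brute-force permutation oracle in the test suite.

#' Minimum-cost assignment of rows to columns
#'
#' Solves the linear assignment problem for an `n x m` cost matrix. When the
#' matrix is rectangular it is padded to square with zero-cost dummy entries;
#' rows assigned to dummy columns come back unassigned. Deterministic: equal-
#' cost optima resolve by the solver's fixed scan order (lowest indices
#' first).
#'
#' @param cost finite numeric matrix.
#' @return integer vector of length `nrow(cost)`; entry i is the assigned
#'   column of row i, or `NA` if unassigned.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !all(is.finite(cost))) {
    stop("cost must be a finite numeric matrix", call. = FALSE)
  }
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  INF <- sum(abs(a)) + 1

  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)              # p[j+1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    if (p[j + 1L] >= 1L && p[j + 1L] <= nr && j <= nc) out[p[j + 1L]] <- j
  }
  out
}

#' Maximum-total-score assignment
#'
#' Convenience wrapper of [solve_assignment()] for score (larger = better)
#' matrices; entries equal to `-Inf` mark forbidden pairs.
#' @param score numeric matrix; `-Inf` allowed for forbidden pairs.
#' @return integer assignment vector as in [solve_assignment()], with
#'   forbidden assignments returned as `NA`.
#' @export
solve_assignment_max <- function(score) {
  if (length(score) == 0L) return(rep(NA_integer_, nrow(score)))
  finite <- is.finite(score)
  big <- if (any(finite)) max(abs(score[finite])) + 1 else 1
  cost <- ifelse(finite, -score, big * max(dim(score)) + 1)
  res <- solve_assignment(cost)
  for (i in seq_along(res)) {
    if (!is.na(res[i]) && !is.finite(score[i, res[i]])) res[i] <- NA_integer_
  }
  res
}
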