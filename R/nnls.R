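#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - y||^2` subject to `x >= 0`. Used to estimate blur
#' vectors from meta-profiles; the problems here are tiny (31 unknowns), so a
#' plain dense active-set implementation is adequate.
#'
#' @param A numeric matrix (m x n).
#' @param y numeric vector of length m.
#' @param tol tolerance on the dual feasibility test; defaults to a scale
#'   relative machine epsilon.
#' @return list with `x` (the solution) and `resid_ss` (residual sum of
#'   squares).
#' @export
nnls_fit <- function(A, y, tol = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(y) == m)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, y))          # gradient at x = 0
  iter_outer <- 0L
  max_outer <- 30L * n
  while (any(!passive & w > tol) && iter_outer < max_outer) {
    iter_outer <- iter_outer + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      # unconstrained LS on the passive set
      z <- numeric(n)
      fit <- qr.coef(qr(A[, P, drop = FALSE]), y)
      fit[is.na(fit)] <- 0
      z[P] <- fit
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  r <- y - drop(A %*% x)
  list(x = x, resid_ss = sum(r^2))
}
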