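# Finite-difference and quadrature primitives shared by the radial solvers.
# All grids are uniform on [0, 1] (rescaled radius r' = r / R(t)).

#' Five-point finite-difference first-derivative matrix
#'
#' Dense differentiation matrix on a uniform grid of `n` nodes with spacing
#' `h`, fourth-order accurate in the interior and at the edges (one-sided
#' five-point stencils for the first/last two rows).
#'
#' @param n number of nodes (>= 5)
#' @param h grid spacing
#' @return an `n x n` matrix `D` such that `D %*% f` approximates `df/dr`
#' @keywords internal
fd_first_matrix <- function(n, h) {
  stopifnot(n >= 5, h > 0)
  D <- matrix(0, n, n)
  # one-sided / skewed stencils at the edges
  D[1, 1:5] <- c(-25, 48, -36, 16, -3) / (12 * h)
  D[2, 1:5] <- c(-3, -10, 18, -6, 1) / (12 * h)
  if (n > 4) {
    for (i in 3:(n - 2)) D[i, (i - 2):(i + 2)] <- c(1, -8, 0, 8, -1) / (12 * h)
  }
  D[n - 1, (n - 4):n] <- c(-1, 6, -18, 10, 3) / (12 * h)
  D[n, (n - 4):n] <- c(3, -16, 36, -48, 25) / (12 * h)
  D
}

#' Five/six-point finite-difference second-derivative matrix
#'
#' Fourth-order accurate; edge rows use six-point one-sided stencils so the
#' whole matrix keeps the interior order.
#'
#' @inheritParams fd_first_matrix
#' @return an `n x n` matrix approximating `d^2/dr^2`
#' @keywords internal
fd_second_matrix <- function(n, h) {
  stopifnot(n >= 6, h > 0)
  D <- matrix(0, n, n)
  h2 <- h^2
  D[1, 1:6] <- c(15 / 4, -77 / 6, 107 / 6, -13, 61 / 12, -5 / 6) / h2
  D[2, 1:6] <- c(5 / 6, -5 / 4, -1 / 3, 7 / 6, -1 / 2, 1 / 12) / h2
  for (i in 3:(n - 2)) D[i, (i - 2):(i + 2)] <- c(-1, 16, -30, 16, -1) / (12 * h2)
  D[n - 1, (n - 5):n] <- rev(c(5 / 6, -5 / 4, -1 / 3, 7 / 6, -1 / 2, 1 / 12)) / h2
  D[n, (n - 5):n] <- rev(c(15 / 4, -77 / 6, 107 / 6, -13, 61 / 12, -5 / 6)) / h2
  D
}

# cache differentiation matrices per (n, h); assembling them is cheap but the
# compressible solver asks for them every step
.fd_cache <- new.env(parent = emptyenv())

fd_ops <- function(n, h) {
  key <- paste0(n, "_", format(h, digits = 17))
  op <- .fd_cache[[key]]
  if (is.null(op)) {
    op <- list(D1 = fd_first_matrix(n, h), D2 = fd_second_matrix(n, h))
    .fd_cache[[key]] <- op
  }
  op
}

#' Second-order upwind gradient
#'
#' Gradient of `f` on a uniform grid where the stencil side follows the sign
#' of the advection velocity at each node (information travels downwind).
#' Falls back to central differencing one node from the relevant edge.
#'
#' @param f field values
#' @param h grid spacing
#' @param vel advection velocity per node; only its sign is used
#' @return gradient approximation, same length as `f`
#' @keywords internal
upwind_gradient <- function(f, h, vel) {
  n <- length(f)
  stopifnot(n >= 4, length(vel) == n)
  g <- numeric(n)
  idx <- seq_len(n)
  pos <- vel >= 0
  # backward-biased (upwind for positive velocity)
  bwd <- numeric(n)
  bwd[idx >= 3] <- (3 * f[idx[idx >= 3]] - 4 * f[idx[idx >= 3] - 1] + f[idx[idx >= 3] - 2]) / (2 * h)
  bwd[2] <- (f[3] - f[1]) / (2 * h)
  bwd[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  # forward-biased (upwind for negative velocity)
  fwd <- numeric(n)
  fwd[idx <= n - 2] <- (-3 * f[idx[idx <= n - 2]] + 4 * f[idx[idx <= n - 2] + 1] - f[idx[idx <= n - 2] + 2]) / (2 * h)
  fwd[n - 1] <- (f[n] - f[n - 2]) / (2 * h)
  fwd[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h)
  g[pos] <- bwd[pos]
  g[!pos] <- fwd[!pos]
  g
}

#' Cumulative trapezoidal integral from the first node
#' @param x abscissae (increasing)
#' @param y ordinates
#' @return vector `I` with `I[1] = 0` and `I[i] = integral of y up to x[i]`
#' @keywords internal
cumtrapz_vec <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' Trapezoidal integral
#' @inheritParams cumtrapz_vec
#' @keywords internal
trapz_vec <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Tridiagonal (Thomas) solve
#'
#' @param lower subdiagonal (length n - 1)
#' @param diag main diagonal (length n)
#' @param upper superdiagonal (length n - 1)
#' @param rhs right-hand side
#' @return solution vector
#' @keywords internal
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  dp <- numeric(n)
  if (abs(diag[1]) < .Machine$double.eps) {
    stop("singular tridiagonal system: zero pivot at row 1")
  }
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    denom <- diag[i] - lower[i - 1] * cp[i - 1]
    if (abs(denom) < .Machine$double.eps * max(1, abs(diag[i]))) {
      stop(sprintf("singular tridiagonal system: zero pivot at row %d", i))
    }
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}
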