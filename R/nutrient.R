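# Nutrient reaction-diffusion on the rescaled moving domain.
#
# The growth factor obeys rho dc/dt = -(gamma_c + gamma) rho c +
# div(D rho grad c) with c = c0 at the moving surface and zero flux at the
# center. On the rescaled grid the advection velocity is
# v_tilde = (v - r Rdot) / R. Diffusion and uptake are treated implicitly
# (tridiagonal solve), advection explicitly with a second-order upwind
# stencil: a first-order operator splitting.

#' One semi-implicit nutrient step
#'
#' Advances the nutrient field by `dt`. For the compressible variant
#' (`rho` varying) the diffusion term uses the conservative face-flux form
#' with face weights `(r_i^2 rho_i + r_{i+1}^2 rho_{i+1}) / 2`; for the
#' incompressible variant (`rho` uniform) the non-conservative central form
#' `D/R^2 (c'' + 2 c'/r)` is used. The center node is regularized by
#' symmetry (`3 c''(0)` for the spherical Laplacian), and the boundary node
#' is pinned at `c0 = 1`. Under the advective step-size restriction the
#' scheme obeys a discrete maximum principle, so `0 < c <= c0`.
#'
#' @param c nutrient field on the rescaled grid
#' @param gamma volumetric growth-rate field (1/day)
#' @param v_tilde rescaled-frame advection velocity `(v - r Rdot)/R`
#' @param rho density field (`rho0/Je`), or a scalar 1 for incompressible
#' @param R current boundary radius
#' @param dt time step (days)
#' @param params a [model_params()]
#' @return the nutrient field at `t + dt`
#' @export
step_nutrient <- function(c, gamma, v_tilde, rho, R, dt, params) {
  N <- length(c)
  stopifnot(N >= 16, R > 0, dt > 0, length(gamma) == N, length(v_tilde) == N)
  if (length(rho) == 1) rho <- rep(rho, N)
  stopifnot(length(rho) == N)
  dr <- 1 / (N - 1)
  r <- seq(0, 1, length.out = N)
  D <- params$L^2
  uniform_rho <- max(abs(rho - rho[1])) < 1e-14

  # explicit advection (2nd-order upwind); v_tilde vanishes at both ends
  adv <- v_tilde * upwind_gradient(c, dr, v_tilde)
  rhs <- rho * (c / dt - adv)

  lower <- numeric(N - 1)
  upper <- numeric(N - 1)
  diagv <- numeric(N)

  # center node: spherical Laplacian limit 3 c''(0); grad(rho).grad(c) = 0
  # there by symmetry
  diagv[1] <- rho[1] / dt + (params$gamma_c + gamma[1]) * rho[1] +
    6 * D * rho[1] / (R^2 * dr^2)
  upper[1] <- -6 * D * rho[1] / (R^2 * dr^2)

  i <- 2:(N - 1)
  if (uniform_rho) {
    # incompressible: central form D/R^2 (c'' + 2 c'/r)
    co_p <- D * rho[i] / R^2 * (1 / dr^2 + 1 / (r[i] * dr))
    co_m <- D * rho[i] / R^2 * (1 / dr^2 - 1 / (r[i] * dr))
  } else {
    # compressible: conservative flux with arithmetic-mean face densities
    wp <- (r[i]^2 * rho[i] + r[i + 1]^2 * rho[i + 1]) / 2
    wm <- (r[i]^2 * rho[i] + r[i - 1]^2 * rho[i - 1]) / 2
    co_p <- D * wp / (r[i]^2 * R^2 * dr^2)
    co_m <- D * wm / (r[i]^2 * R^2 * dr^2)
  }
  upper[i] <- -co_p
  lower[i - 1] <- -co_m
  diagv[i] <- rho[i] / dt + (params$gamma_c + gamma[i]) * rho[i] + co_p + co_m

  # boundary node pinned at c0
  diagv[N] <- 1
  lower[N - 1] <- 0
  rhs[N] <- params$c0

  cn <- thomas_solve(lower, diagv, upper, rhs)
  if (any(!is.finite(cn))) stop("nutrient solve produced non-finite values")
  cn
}

#' Closed-form steady nutrient profile
#'
#' Steady state of `D laplacian(c) = gamma_c c` in a ball of radius `R` with
#' `c(R) = c0`: `c(r) = c0 (R/r) sinh(r/l) / sinh(R/l)` with penetration
#' length `l = L / sqrt(gamma_c)`; the center value is the limit
#' `c0 (R/l) / sinh(R/l)`. Used by the equilibrium shooting analysis, where
#' growth has stopped and the domain is stationary.
#'
#' @param r radius (lab frame, same units as `R`); vectorized
#' @param R spheroid radius
#' @param params a [model_params()]
#' @return concentration at `r`
#' @examples
#' p <- model_params(L = 65, gamma_c = 0.7)
#' steady_nutrient_profile(0, 100, p)  # ~0.769
#' @export
steady_nutrient_profile <- function(r, R, params) {
  stopifnot(R > 0, all(r >= 0), all(r <= R * (1 + 1e-6)))
  r <- pmin(r, R)  # adaptive ODE callers may probe marginally past R
  if (params$gamma_c == 0) {
    return(rep(params$c0, length(r)))
  }
  ell <- params$L / sqrt(params$gamma_c)
  out <- numeric(length(r))
  small <- r < 1e-10 * R
  # sinh ratio written via exp to stay finite for large arguments
  ratio <- function(a, b) {
    # sinh(a)/sinh(b), 0 <= a <= b
    exp(a - b) * (1 - exp(-2 * a)) / (1 - exp(-2 * b))
  }
  out[!small] <- params$c0 * (R / r[!small]) * ratio(r[!small] / ell, R / ell)
  out[small] <- params$c0 * (R / ell) * 2 * exp(-R / ell) / (1 - exp(-2 * R / ell))
  out
}

# analytic radial derivative of the steady profile (lab frame), used by the
# equilibrium shooting ODE
steady_nutrient_gradient <- function(r, R, params) {
  if (params$gamma_c == 0) {
    return(rep(0, length(r)))
  }
  ell <- params$L / sqrt(params$gamma_c)
  sh <- function(x) sinh(x)
  out <- params$c0 * R / sinh(R / ell) *
    (cosh(r / ell) / (ell * r) - sinh(r / ell) / r^2)
  out[r < 1e-10 * R] <- 0
  out
}
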