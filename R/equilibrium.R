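# Steady states of the incompressible model without rearrangement (beta = 0)
# by shooting.
#
# At equilibrium the growth rate vanishes everywhere, which with the radial
# force balance gives a closed system for the hoop stretch profile and the
# radius: differentiating the zero-growth relation
#     W + p - I1/3 = (k/2) c(R, r)^2
# in r and eliminating dp/dr with the force balance yields a scalar ODE for
# fetheta(r). The center is isotropic (fetheta(0) = 1) and regular, with the
# local expansion fetheta ~ 1 - k c(0)^2 r^2 / (60 l^2); integrating OUTWARD
# from the center is numerically stable (the inward direction amplifies
# center errors like (R/r)^3), and the remaining unknown R must satisfy the
# surface relation
#     Fext = k/2 - W - (2/3)(fetheta^-4 - fetheta^2)   at r = R,
# whose right side lies in [0, k/2] for fetheta in (0, 1]. This bound is the
# origin of the constant-pressure existence threshold Pext = k/2. The
# shooting residual is therefore the required-minus-actual traction at the
# surface, a smooth function of R.

# h(f) = W(f) + (2/3)(f^-4 - f^2) = (7/6) f^-4 + f^2/3 - 3/2, strictly
# decreasing on (0, 1] from +Inf to 0; Fext = k/2 - h(f) at the surface
.boundary_gap <- function(f, params) {
  (7 / 6) * params$mu * f^-4 + params$mu * f^2 / 3 - 1.5 * params$mu
}

# surface hoop stretch in (0, 1] for a given compressive traction, or NA
# when Fext > k/2 (no balance possible)
equilibrium_surface_stretch <- function(Fext, params) {
  target <- params$k / 2 - Fext
  if (target < 0) return(NA_real_)
  if (target == 0) return(1)
  f_lo <- 0.9
  while (.boundary_gap(f_lo, params) < target && f_lo > 1e-6) f_lo <- f_lo / 2
  stats::uniroot(function(f) .boundary_gap(f, params) - target,
                 c(f_lo, 1), tol = 1e-14)$root
}

# outward integration of the hoop-stretch ODE from the regular center
# expansion at r0 = r_min_frac * R up to r = R
.shoot_outward <- function(R, params, r_min_frac = 1e-3, dense = FALSE) {
  mu <- params$mu
  k <- params$k
  derivs <- function(r, y, parms) {
    f <- y[1]
    rc <- min(r, R)  # the adaptive solver may probe marginally past R
    c_val <- steady_nutrient_profile(rc, R, params)
    c_grad <- steady_nutrient_gradient(rc, R, params)
    num <- k * c_val * c_grad - (2 / r) * mu * (f^-4 - f^2)
    den <- (2 / 3) * mu * (f - 7 * f^-5)
    list(num / den)
  }
  r0 <- r_min_frac * R
  c0v <- steady_nutrient_profile(0, R, params)
  ell2 <- if (params$gamma_c > 0) params$L^2 / params$gamma_c else Inf
  f0 <- 1 - k * c0v^2 * r0^2 / (60 * mu * ell2)
  rootfun <- function(r, y, parms) y[1] - 0.02
  rr <- if (dense) seq(r0, R, length.out = 400) else c(r0, R)
  suppressWarnings(
    deSolve::ode(y = c(f = f0), times = rr, func = derivs,
                 rootfunc = rootfun, method = "lsodar",
                 rtol = 1e-11, atol = 1e-12, maxsteps = 20000))
}

# required-minus-actual surface traction; roots are equilibria
.shoot_residual <- function(R, params, Fext_fun, r_min_frac) {
  sol <- .shoot_outward(R, params, r_min_frac)
  f_R <- unname(sol[nrow(sol), "f"])
  if (f_R <= 0.02 || abs(sol[nrow(sol), "time"] - R) > 1e-8 * R) {
    # profile collapsed before reaching the surface: the required traction
    # is far above anything attainable
    return(-Inf)
  }
  (params$k / 2 - .boundary_gap(f_R, params)) - Fext_fun(R)
}

#' Equilibrium spheroid by shooting
#'
#' Computes the steady radius and hoop-stretch profile of the incompressible
#' model without rearrangement under a gel or pressure load. On success the
#' returned profile satisfies the zero-growth relation pointwise, the radial
#' force balance with surface stress `-Fext(R_star)`, and center isotropy
#' `fetheta(0) = 1`. When no equilibrium exists (free boundary, or a
#' constant pressure above `k/2`) a non-converged result with a diagnosed
#' reason is returned.
#'
#' @param params a [model_params()]; must have `beta = 0`
#' @param load a [boundary_load()]
#' @param R_bracket radius search bracket (defaults to
#'   `[max(R0_gel, L/1000), 50 L]`)
#' @param n_scan number of log-spaced radii scanned for a sign change
#' @param r_min_frac inner matching radius of the outward integration, as a
#'   fraction of the radius (the center is entered through its regular
#'   series expansion)
#' @return an object of class `equilibrium_solution` with `R_star`,
#'   `r` (lab-frame grid), `fetheta_profile`, `p_profile`, `c_profile`,
#'   `converged`, `residual` (surface traction defect), `reason`
#' @examples
#' \donttest{
#' p <- model_params(k = 1, eta = 1, gamma_c = 0.7, L = 65, beta = 0)
#' eq <- shoot_equilibrium(p, boundary_load("gel", cH = 0.5, R0_gel = 20))
#' eq$R_star
#' }
#' @export
shoot_equilibrium <- function(params, load, R_bracket = NULL, n_scan = 80,
                              r_min_frac = 1e-3) {
  if (params$beta != 0) {
    stop("the equilibrium analysis applies to the beta = 0 model only")
  }
  no_eq <- function(reason) {
    structure(list(R_star = NA_real_, r = NULL, fetheta_profile = NULL,
                   p_profile = NULL, c_profile = NULL, converged = FALSE,
                   residual = NA_real_, reason = reason),
              class = "equilibrium_solution")
  }
  if (load$kind == "free" ||
      (load$kind == "gel" && load$cH == 0) ||
      (load$kind == "pressure" && load$Pext == 0)) {
    return(no_eq(paste("no equilibrium: the surface traction vanishes, so",
                       "force balance at the center cannot hold and the",
                       "spheroid grows without bound")))
  }
  if (load$kind == "pressure" && load$Pext > params$k / 2) {
    return(no_eq(sprintf(
      "no equilibrium: Pext = %g exceeds the existence threshold k/2 = %g; the radius shrinks to zero",
      load$Pext, params$k / 2)))
  }
  Fext_fun <- function(R) external_traction(load, R, t = 0)
  if (is.null(R_bracket)) {
    lo <- if (load$kind == "gel") load$R0_gel * (1 + 1e-6) else params$L / 1000
    R_bracket <- c(lo, 50 * params$L)
  }
  Rs <- exp(seq(log(R_bracket[1]), log(R_bracket[2]), length.out = n_scan))
  res <- vapply(Rs, .shoot_residual, numeric(1),
                params = params, Fext_fun = Fext_fun,
                r_min_frac = r_min_frac)
  sc <- which(diff(sign(res)) != 0)
  if (length(sc) == 0) {
    return(no_eq("no equilibrium: the required surface traction never meets the applied one inside the bracket"))
  }
  i <- sc[1]
  root <- stats::uniroot(
    .shoot_residual, interval = c(Rs[i], Rs[i + 1]),
    f.lower = res[i], f.upper = res[i + 1],
    params = params, Fext_fun = Fext_fun, r_min_frac = r_min_frac,
    tol = 1e-12 * Rs[i + 1])
  R_star <- root$root

  Fext <- Fext_fun(R_star)
  sol <- .shoot_outward(R_star, params, r_min_frac, dense = TRUE)
  r <- sol[, "time"]
  f <- sol[, "f"]
  c_prof <- steady_nutrient_profile(r, R_star, params)
  I1 <- f^-4 + 2 * f^2
  W <- 0.5 * params$mu * (I1 - 3)
  # pressure from the zero-growth relation; by construction it also solves
  # the radial force balance with p(R) = fetheta(R)^-4 + Fext
  p <- 0.5 * params$k * c_prof^2 + params$mu * I1 / 3 - W

  structure(
    list(R_star = R_star, r = r, fetheta_profile = f, p_profile = p,
         c_profile = c_prof, converged = TRUE,
         residual = abs((params$k / 2 - .boundary_gap(f[length(f)], params)) -
                          Fext),
         Fext = Fext, reason = NULL),
    class = "equilibrium_solution"
  )
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "equilibrium: R* = %.6g um (surface residual %.2e, Fext = %.4g)\n",
      x$R_star, x$residual, x$Fext))
    cat(sprintf("  fetheta in [%.4g, %.4g]\n",
                min(x$fetheta_profile), max(x$fetheta_profile)))
  } else {
    cat("no equilibrium found\n  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' Existence threshold for a constant-pressure load
#'
#' The largest constant compressive pressure under which a finite
#' equilibrium radius exists: at the surface the zero-growth relation and
#' force balance require `Fext = k/2 - W - (2/3)(fetheta^-4 - fetheta^2)`
#' with `fetheta in (0, 1]`, whose right side is at most `k/2`. Above
#' `Pext = k/2` the internal stress cannot balance the load and the radius
#' shrinks to zero.
#'
#' @param params a [model_params()]
#' @return the threshold pressure `k/2`
#' @export
existence_threshold <- function(params) params$k / 2

# center-consistency diagnostic of a converged solution: the pressure from
# the force-balance quadrature (anchored at the surface) must meet the
# zero-growth pressure at the innermost point
equilibrium_center_residual <- function(eq, params) {
  stopifnot(eq$converged)
  r <- eq$r
  f <- eq$fetheta_profile
  srr <- params$mu * f^-4
  sdiff <- params$mu * (f^-4 - f^2)
  I <- trapz_vec(r, 2 * sdiff / r)
  p_R <- srr[length(r)] + eq$Fext
  p0_balance <- p_R - (srr[length(r)] - srr[1]) - I
  p0_growth <- eq$p_profile[1]
  abs(p0_balance - p0_growth)
}
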