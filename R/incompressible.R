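# Incompressible radial solver.
#
# State: hoop stretch fetheta (fer = fetheta^-2 by Je = 1), pressure p,
# nutrient c, radius R, on the rescaled grid r in [0, 1]. Each step:
#   1. elastic stresses from fetheta;
#   2. coupled pressure / growth-rate / velocity pass:
#        p from the radial force balance integrated inward from the boundary
#          condition p(1) = fer(1)^2 + Fext,
#        gamma from the feedback law with that p,
#        v from incompressibility, v = (R/r^2) int_0^r gamma s^2 ds;
#      iterated to a fixed point (p does not depend on v or gamma, so the
#      pass converges immediately; the loop guards the contract);
#   3. explicit Euler update of fetheta (2nd-order upwind advection) and R;
#   4. semi-implicit nutrient step.

#' Solver controls for the incompressible variant
#'
#' @param N grid nodes
#' @param dt time step (days)
#' @param tol residual tolerance of the velocity-pressure-growth pass
#' @param max_iter iteration cap before declaring non-convergence
#' @param snapshot_every store a full state snapshot every this many steps
#' @param audit_every record the audit scalar series every this many steps
#'   (1 gives step-resolved conservation audits; raise it for fitting runs
#'   where only the radius series matters)
#' @return a list of class `incompressible_control`
#' @export
incompressible_control <- function(N = 64, dt = 5e-3, tol = 1e-6,
                                   max_iter = 100, snapshot_every = 100,
                                   audit_every = 1) {
  stopifnot(N >= 16, dt > 0, tol > 0, max_iter >= 1, snapshot_every >= 1,
            audit_every >= 1)
  structure(list(N = N, dt = dt, tol = tol, max_iter = max_iter,
                 snapshot_every = snapshot_every, audit_every = audit_every),
            class = "incompressible_control")
}

#' Velocity from the incompressibility constraint
#'
#' `div v = gamma` in radial symmetry gives
#' `v(r') = (R / r'^2) int_0^{r'} gamma(s) s^2 ds` on the rescaled grid
#' (equivalently `v(r) = 1/r^2 int_0^r gamma s^2 ds` in the lab frame).
#' Trapezoidal quadrature (second order); `v(0) = 0`.
#'
#' @param gamma growth-rate field on the rescaled grid
#' @param R boundary radius
#' @return lab-frame radial velocity sampled on the rescaled grid
#' @export
velocity_from_growth <- function(gamma, R) {
  N <- length(gamma)
  r <- seq(0, 1, length.out = N)
  # moment quadrature exact for piecewise-linear gamma: plain trapezoid on
  # gamma * s^2 misrepresents the s^2 weight near the origin (50% error on
  # the first interval), which feeds straight into v/r at the second node
  a <- r[-N]
  b <- r[-1]
  h <- b - a
  i3 <- (b^3 - a^3) / 3
  i4 <- (b^4 - a^4) / 4
  wa <- (b * i3 - i4) / h
  wb <- (i4 - a * i3) / h
  I <- c(0, cumsum(wa * gamma[-N] + wb * gamma[-1]))
  v <- numeric(N)
  v[-1] <- R * I[-1] / r[-1]^2
  v
}

#' Pressure from the radial force balance
#'
#' Integrates `dp/dr = d(sigma_rr^e)/dr + (2/r)(sigma_rr^e - sigma_tt^e)`
#' (elastic parts `fer^2 = fetheta^-4` and `fetheta^2`) inward from the
#' boundary condition `p(1) = fer(1)^2 + Fext`, so the total radial stress
#' at the surface is exactly `-Fext`. The `2/r` term uses its symmetric
#' limit at the center (the elastic stress difference vanishes there
#' quadratically).
#'
#' @param fetheta hoop stretch field on the rescaled grid
#' @param Fext compressive traction at the surface
#' @return pressure field
#' @export
pressure_from_balance <- function(fetheta, Fext) {
  N <- length(fetheta)
  stopifnot(N >= 5)
  r <- seq(0, 1, length.out = N)
  dr <- r[2] - r[1]
  srr <- fetheta^-4
  sdiff <- srr - fetheta^2
  D1 <- fd_ops(N, dr)$D1
  rhs <- drop(D1 %*% srr)
  # (2/r) sdiff -> 2 * d(sdiff)/dr at r = 0 (sdiff(0) = 0 by isotropy)
  rhs[-1] <- rhs[-1] + 2 * sdiff[-1] / r[-1]
  rhs[1] <- rhs[1] + 2 * drop(D1[1, ] %*% sdiff)
  p_end <- fetheta[N]^-4 + Fext
  # inward cumulative integral: p(r) = p(1) - int_r^1 rhs
  I <- cumtrapz_vec(r, rhs)
  p_end - (I[N] - I)
}

# rescaled-frame advection velocity
vtilde_field <- function(v, r, R) (v - r * v[length(v)]) / R

# coupled pressure / growth-rate / velocity pass. The pressure depends only
# on the strains and the traction, so the fixed point is reached in one
# sweep; the loop re-evaluates gamma and v until the update norm drops
# below tol, guarding the contract for any future coupling.
solve_vpg_incompressible <- function(fetheta, c, Fext, R, params, control,
                                     p_init = NULL) {
  p <- if (is.null(p_init)) pressure_from_balance(fetheta, Fext) else p_init
  gamma <- NULL
  v <- NULL
  resid_hist <- numeric(0)
  for (it in seq_len(control$max_iter)) {
    gamma_new <- growth_rate_incompressible(c, p, fetheta, params)
    v_new <- velocity_from_growth(gamma_new, R)
    resid <- if (is.null(gamma)) Inf else {
      max(max(abs(gamma_new - gamma)), max(abs(v_new - v)))
    }
    gamma <- gamma_new
    v <- v_new
    resid_hist <- c(resid_hist, resid)
    if (resid < control$tol) break
  }
  if (resid_hist[length(resid_hist)] >= control$tol) {
    stop(sprintf(
      "velocity-pressure iteration did not converge (last residual %.3e); history: %s",
      resid_hist[length(resid_hist)],
      paste(format(resid_hist, digits = 3), collapse = ", ")))
  }
  list(p = p, gamma = gamma, v = v, iterations = length(resid_hist))
}

#' One incompressible time step
#'
#' Advances a [radial_state()] by `control$dt` under `params` and `load`.
#' Postconditions: `fer * fetheta^2 = 1` to machine precision (fer is
#' recomputed from fetheta), the stored pressure satisfies
#' `p(1) = fer(1)^2 + Fext` exactly, and `R` is advanced by the boundary
#' velocity.
#'
#' @param state a [radial_state()]
#' @param params a [model_params()]
#' @param load a [boundary_load()]
#' @param control an [incompressible_control()]
#' @return the state at `t + dt`
#' @export
step_incompressible <- function(state, params, load, control) {
  N <- length(state$r_grid)
  r <- state$r_grid
  dr <- r[2] - r[1]
  fetheta <- state$fetheta
  R <- state$R

  Fext <- external_traction(load, R, state$t)
  # the stored pressure (if any) already solves the balance for this state:
  # step_incompressible writes it from the updated strains and traction
  sol <- solve_vpg_incompressible(fetheta, state$c, Fext, R, params, control,
                                  p_init = state$p)
  v <- sol$v
  gamma <- sol$gamma

  vt <- vtilde_field(v, r, R)
  # v/(r R) with its center limit gamma/3 (v ~ R gamma(0) r / 3 near 0)
  vor <- numeric(N)
  vor[-1] <- v[-1] / (r[-1] * R)
  vor[1] <- gamma[1] / 3

  adv <- vt * upwind_gradient(fetheta, dr, vt)
  fer <- fetheta^-2
  src <- (vor - gamma / 3 - (params$beta / 3) * (fetheta^2 - fer^2)) * fetheta
  fetheta_new <- fetheta + control$dt * (src - adv)
  if (any(fetheta_new <= 0)) {
    stop("hoop stretch became non-positive; reduce dt")
  }
  R_new <- R + control$dt * v[N]

  c_new <- step_nutrient(state$c, gamma, vt, 1, R, control$dt, params)

  # store the pressure consistent with the updated strains and radius so the
  # boundary condition p(1) = fer(1)^2 + Fext holds on every stored state
  t_new <- state$t + control$dt
  p_store <- pressure_from_balance(
    fetheta_new, external_traction(load, R_new, t_new))

  radial_state(
    N = N, R = R_new, fer = fetheta_new^-2, fetheta = fetheta_new,
    c = pmin(c_new, params$c0), p = p_store, t = t_new
  )
}
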