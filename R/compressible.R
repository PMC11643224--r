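# Compressible radial solver.
#
# The mechanical equilibrium div(sigma) = 0 does not involve the velocity,
# so the velocity is revealed by taking the time derivative of the force
# balance and adding an artificial damping beta_tilde that pulls the
# residual back to zero:
#     d/dt (div sigma) + beta_tilde * div sigma = 0.
# Substituting the strain evolution laws and the constitutive derivatives
# turns this into a linear second-order equation for the velocity,
#     a1 v + a2 v' + a3 v'' + a8 v(1) + a4 = 0   in the bulk,
#     a5 v' + a6 v       = a7                     at r = 1,
# where the nonlocal a8 term comes from the moving rescaled frame
# (v_tilde = (v - r Rdot)/R with Rdot = v(1)). The coefficients are the
# exact chain-rule substitution of the evolution laws into the
# differentiated force balance, evaluated with five-point finite
# differences; their correctness is gated by a finite-difference-in-time
# oracle (see surrogate_residual_check).

#' Solver controls for the compressible variant
#'
#' @param N grid nodes
#' @param dt time step (days); `NULL` picks `min(1e-3, 1/beta_tilde)`, the
#'   stability bound of the explicitly damped residual
#' @param beta_tilde artificial damping rate (1/day) of the surrogate
#'   velocity equation. The residual floor of the damped scheme is the
#'   stress rate over `beta_tilde`, and stress rates grow with the bulk
#'   modulus, so the `NULL` default resolves to `max(1e3, 10 K)` once the
#'   parameters are known; a doubling retry guards drifts past `eps_fb`.
#' @param eps_fb force-balance residual ceiling, as a fraction of the
#'   stress scale
#' @param snapshot_every store a snapshot every this many steps
#' @param audit_every record the audit scalar series every this many steps
#' @return a list of class `compressible_control`
#' @export
compressible_control <- function(N = 64, dt = NULL, beta_tilde = NULL,
                                 eps_fb = 1e-4, snapshot_every = 100,
                                 audit_every = 1) {
  stopifnot(N >= 16, is.null(dt) || dt > 0,
            is.null(beta_tilde) || beta_tilde > 0,
            eps_fb > 0, snapshot_every >= 1, audit_every >= 1)
  structure(list(N = N, dt = dt, beta_tilde = beta_tilde, eps_fb = eps_fb,
                 snapshot_every = snapshot_every, audit_every = audit_every),
            class = "compressible_control")
}

# fill NULL damping/step entries from the parameters
resolve_compressible_control <- function(control, params) {
  if (is.null(control$beta_tilde)) {
    control$beta_tilde <- max(1e3, 10 * params$K)
  }
  if (is.null(control$dt)) {
    control$dt <- min(1e-3, 1 / control$beta_tilde)
  }
  control
}

# partial derivatives of sigma_rr and sigma_s = sigma_rr - sigma_tt with
# respect to the two stretches (mu = 1 scale kept explicit)
.stress_partials <- function(fer, fetheta, params) {
  mu <- params$mu
  K <- params$K
  Je <- fer * fetheta^2
  S <- Je^(-5 / 3)
  S8 <- Je^(-8 / 3)
  dif <- fer^2 - fetheta^2
  list(
    Je = Je, S = S,
    sigma_rr = (2 / 3) * mu * S * dif + K * (Je - 1),
    sigma_s = mu * S * dif,
    Arr = (2 / 3) * mu * (-(5 / 3) * S8 * fetheta^2 * dif + 2 * fer * S) +
      K * fetheta^2,
    Brr = (2 / 3) * mu * (-(5 / 3) * S8 * 2 * fer * fetheta * dif -
                            2 * fetheta * S) + 2 * K * fer * fetheta,
    As = mu * (-(5 / 3) * S8 * fetheta^2 * dif + 2 * fer * S),
    Bs = mu * (-(10 / 3) * S8 * fer * fetheta * dif - 2 * fetheta * S)
  )
}

# discrete force-balance residual G = d(sigma_rr)/dr + (2/r) sigma_s on the
# rescaled grid (the common 1/R factor of the lab-frame balance is dropped);
# the center value uses the symmetric limit 2 * d(sigma_s)/dr
force_balance_residual <- function(fer, fetheta, params) {
  N <- length(fer)
  r <- seq(0, 1, length.out = N)
  dr <- r[2] - r[1]
  sp <- .stress_partials(fer, fetheta, params)
  D1 <- fd_ops(N, dr)$D1
  G <- drop(D1 %*% sp$sigma_rr)
  G[-1] <- G[-1] + 2 * sp$sigma_s[-1] / r[-1]
  G[1] <- G[1] + 2 * drop(D1[1, ] %*% sp$sigma_s)
  G
}

#' Assemble the damped velocity system
#'
#' Builds the coefficient fields of the surrogate velocity equation from the
#' current state: `a1 v + a2 v' + a3 v'' + a8 v(1) + a4 = 0` in the bulk and
#' `a5 v' + a6 v = a7` at the surface, plus the pinned center `v(0) = 0`.
#'
#' @param state a [radial_state()]
#' @param params a [model_params()]
#' @param load a [boundary_load()]
#' @param control a [compressible_control()]
#' @return a list of class `velocity_system` with the coefficient fields,
#'   the growth-rate field and the residual `G`
#' @export
assemble_velocity_system <- function(state, params, load, control) {
  control <- resolve_compressible_control(control, params)
  N <- length(state$r_grid)
  stopifnot(N >= 5)
  r <- state$r_grid
  dr <- r[2] - r[1]
  R <- state$R
  fer <- state$fer
  fetheta <- state$fetheta
  ops <- fd_ops(N, dr)
  D1 <- ops$D1
  D2 <- ops$D2

  sp <- .stress_partials(fer, fetheta, params)
  gamma <- growth_rate_compressible(state$c, fer, fetheta, params)

  # velocity-free parts of the strain evolution laws
  phi_r <- -(gamma / 3 + (2 * params$beta / 3) * (fer^2 - fetheta^2)) * fer
  phi_t <- -(gamma / 3 + (params$beta / 3) * (fetheta^2 - fer^2)) * fetheta

  P1 <- sp$Arr * fer        # multiplies v'/R in d(sigma_rr)/dt
  P2 <- sp$Brr * fetheta    # multiplies v/(rR)
  Q1 <- sp$As * fer
  Q2 <- sp$Bs * fetheta
  Cpi <- sp$Arr * phi_r + sp$Brr * phi_t
  Cs <- sp$As * phi_r + sp$Bs * phi_t

  srr_r <- drop(D1 %*% sp$sigma_rr)
  srr_rr <- drop(D2 %*% sp$sigma_rr)
  ss_r <- drop(D1 %*% sp$sigma_s)
  P1_r <- drop(D1 %*% P1)
  P2_r <- drop(D1 %*% P2)
  Cpi_r <- drop(D1 %*% Cpi)

  G <- srr_r
  G[-1] <- G[-1] + 2 * sp$sigma_s[-1] / r[-1]
  G[1] <- G[1] + 2 * ss_r[1]

  bt <- control$beta_tilde
  ri <- r
  ri[1] <- NA_real_  # center row is replaced by v(0) = 0; avoid 0/0

  a3 <- P1 / R
  a2 <- (-srr_r + P1_r + P2 / ri + 2 * Q1 / ri) / R
  a1 <- (-srr_rr - 2 * ss_r / ri + P2_r / ri - P2 / ri^2 + 2 * Q2 / ri^2) / R
  a8 <- (srr_r + ri * srr_rr + 2 * ss_r) / R
  a4 <- Cpi_r + 2 * Cs / ri + bt * G

  if (any(abs(a3[-1]) < 1e-12)) {
    stop("degenerate velocity system: vanishing second-order coefficient")
  }

  Fext <- external_traction(load, R, state$t)
  dFdR <- external_traction_dR(load, R, state$t)
  a5 <- P1[N] / R
  a6 <- P2[N] / R + dFdR
  a7 <- -Cpi[N] - bt * (sp$sigma_rr[N] + Fext)

  structure(
    list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6, a7 = a7,
         a8 = a8, G = G, gamma = gamma, N = N, dr = dr, R = R,
         D1 = D1, D2 = D2),
    class = "velocity_system"
  )
}

#' Solve the assembled velocity system
#'
#' Dense linear solve with the center pinned (`v(0) = 0`), five-point
#' difference stencils for `v'` and `v''`, and the damped traction
#' condition as the last row.
#'
#' @param system a `velocity_system` from [assemble_velocity_system()]
#' @return the velocity field (lab-frame, on the rescaled grid)
#' @export
solve_velocity <- function(system) {
  N <- system$N
  A <- matrix(0, N, N)
  b <- numeric(N)
  A[1, 1] <- 1
  i <- 2:(N - 1)
  A[i, ] <- system$a2[i] * system$D1[i, ] + system$a3[i] * system$D2[i, ]
  A[cbind(i, i)] <- A[cbind(i, i)] + system$a1[i]
  A[i, N] <- A[i, N] + system$a8[i]
  b[i] <- -system$a4[i]
  A[N, ] <- system$a5 * system$D1[N, ]
  A[N, N] <- A[N, N] + system$a6
  b[N] <- system$a7
  v <- tryCatch(solve(A, b), error = function(e) {
    stop(sprintf("velocity solve failed (%s); reciprocal condition ~ %.2e",
                 conditionMessage(e), rcond(A)))
  })
  resid <- max(abs(A %*% v - b)) / max(1, max(abs(b)))
  if (resid > 1e-10) {
    stop(sprintf("velocity linear-system residual %.2e exceeds 1e-10", resid))
  }
  v
}

# stress scale used to normalize the force-balance residual
.stress_scale <- function(sp, params) {
  max(params$mu, max(abs(sp$sigma_rr)), max(abs(sp$sigma_s)))
}

#' One compressible time step
#'
#' Solves the damped velocity system, updates the stretches by explicit
#' Euler with second-order upwind advection, advances the radius by the
#' boundary velocity, and makes a semi-implicit nutrient step with the
#' density `rho0/Je` of the same time level. The force-balance residual is
#' monitored; a blow-up beyond ten times the ceiling aborts with advice.
#'
#' @inheritParams assemble_velocity_system
#' @return the state at `t + dt`, with attribute `fb_residual` (normalized
#'   force-balance residual after the step)
#' @export
step_compressible <- function(state, params, load, control) {
  control <- resolve_compressible_control(control, params)
  N <- length(state$r_grid)
  r <- state$r_grid
  dr <- r[2] - r[1]
  R <- state$R

  system <- assemble_velocity_system(state, params, load, control)
  v <- solve_velocity(system)
  gamma <- system$gamma

  vt <- vtilde_field(v, r, R)
  vr <- drop(system$D1 %*% v)
  vor <- numeric(N)
  vor[-1] <- v[-1] / (r[-1] * R)
  vor[1] <- vr[1] / R

  fer <- state$fer
  fetheta <- state$fetheta
  adv_r <- vt * upwind_gradient(fer, dr, vt)
  adv_t <- vt * upwind_gradient(fetheta, dr, vt)
  src_r <- (vr / R - gamma / 3 -
              (2 * params$beta / 3) * (fer^2 - fetheta^2)) * fer
  src_t <- (vor - gamma / 3 -
              (params$beta / 3) * (fetheta^2 - fer^2)) * fetheta
  fer_new <- fer + control$dt * (src_r - adv_r)
  fetheta_new <- fetheta + control$dt * (src_t - adv_t)
  if (any(fer_new <= 0) || any(fetheta_new <= 0)) {
    stop("elastic stretch became non-positive; reduce dt")
  }
  # center isotropy is preserved analytically (both rates use v'(0)); pin it
  # against roundoff drift
  iso <- (fer_new[1] + fetheta_new[1]) / 2
  fer_new[1] <- iso
  fetheta_new[1] <- iso

  R_new <- R + control$dt * v[N]
  rho <- params$rho0 / (fer * fetheta^2)
  c_new <- step_nutrient(state$c, gamma, vt, rho, R, control$dt, params)

  out <- radial_state(
    N = N, R = R_new, fer = fer_new, fetheta = fetheta_new,
    c = pmin(c_new, params$c0), p = NULL, t = state$t + control$dt
  )
  # residual of the discrete force-balance system: the bulk equation on the
  # interior nodes where it is imposed, plus the traction defect at the
  # surface node (which carries the boundary's share of the balance). The
  # center node is a symmetry closure (v(0) = 0), not an equation row.
  sp_new <- .stress_partials(fer_new, fetheta_new, params)
  G_new <- force_balance_residual(fer_new, fetheta_new, params)
  Fext_new <- external_traction(load, R_new, out$t)
  traction_defect <- abs(sp_new$sigma_rr[N] + Fext_new)
  attr(out, "fb_residual") <-
    max(max(abs(G_new[2:(N - 1)])), traction_defect) /
    .stress_scale(sp_new, params)
  out
}

#' Finite-difference oracle for the surrogate velocity equation
#'
#' Advances a copy of the state by a tiny step `delta` with the computed
#' velocity and compares the observed decay rate of the force-balance
#' residual against the imposed damping: the surrogate construction demands
#' `(G(t + delta) - G(t)) / delta = -beta_tilde G(t)`. Returns the observed
#' and imposed rates; their relative mismatch is the correctness gate of the
#' coefficient assembly.
#'
#' @inheritParams assemble_velocity_system
#' @param delta probe step (days); small enough that one-step time
#'   discretization error is negligible against the decay itself
#' @return list with `rate_observed`, `rate_imposed = beta_tilde`,
#'   `relative_mismatch`, and the residual norms before/after
#' @export
surrogate_residual_check <- function(state, params, load, control,
                                     delta = 1e-6) {
  probe <- resolve_compressible_control(control, params)
  probe$dt <- delta
  N <- length(state$r_grid)
  keep <- 2:(N - 1)  # rows where the damped bulk equation is imposed
  G0 <- force_balance_residual(state$fer, state$fetheta, params)[keep]
  st1 <- step_compressible(state, params, load, probe)
  G1 <- force_balance_residual(st1$fer, st1$fetheta, params)[keep]
  # project the observed rate of change onto the residual direction
  num <- sum(G0 * (G1 - G0)) / delta
  den <- sum(G0 * G0)
  if (den == 0) {
    return(list(rate_observed = 0, rate_imposed = probe$beta_tilde,
                relative_mismatch = 0, norm_before = 0,
                norm_after = sqrt(sum(G1^2))))
  }
  rate <- -num / den
  list(
    rate_observed = rate,
    rate_imposed = probe$beta_tilde,
    relative_mismatch = abs(rate - probe$beta_tilde) / probe$beta_tilde,
    norm_before = sqrt(den),
    norm_after = sqrt(sum(G1^2))
  )
}
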