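# Time-stepping driver shared by the two variants; produces a trajectory
# object carrying the radius series, sparse state snapshots and per-step
# audit scalars (mass, energies, dissipation bounds, force-balance
# residual).

# per-step scalar audit quantities; integrals use the rescaled measure
# dV = 4 pi R^3 r^2 dr
audit_scalars <- function(state, params, variant, load) {
  r <- state$r_grid
  N <- length(r)
  dr <- r[2] - r[1]
  R <- state$R
  fer <- state$fer
  fetheta <- state$fetheta
  vol <- 4 * pi * R^3

  if (variant == "compressible") {
    Je <- fer * fetheta^2
    rho <- params$rho0 / Je
    W <- strain_energy_density(fer, fetheta, params)
    s <- cauchy_stress_radial(fer, fetheta, params)
    srr <- s$sigma_rr
    stt <- s$sigma_tt
    gamma <- growth_rate_compressible(state$c, fer, fetheta, params)
    bracket <- 0.5 * params$k * rho * state$c^2 + params$K * (Je - 1) - W / Je
    Wvol <- W / Je
  } else {
    Je <- rep(1, N)
    rho <- rep(params$rho0, N)
    W <- strain_energy_density(fer, fetheta, params, incompressible = TRUE)
    srr <- params$mu * fetheta^-4 - state$p
    stt <- params$mu * fetheta^2 - state$p
    gamma <- growth_rate_incompressible(state$c, state$p, fetheta, params)
    I1 <- fetheta^-4 + 2 * fetheta^2
    bracket <- 0.5 * params$k * state$c^2 + params$mu * I1 / 3 - state$p - W
    Wvol <- W
  }
  sN <- (srr + 2 * stt) / 3
  gam_d <- rearrangement_rates_radial(fer, fetheta, params$beta)
  diss_pt <- (srr - sN) * gam_d$Gamma_rr + 2 * (stt - sN) * gam_d$Gamma_tt
  Q_pt <- -gamma * rho * bracket

  D1 <- fd_ops(N, dr)$D1
  c_r <- drop(D1 %*% state$c)
  D <- params$L^2
  k <- params$k

  list(
    t = state$t, R = R,
    mass = vol * trapz_vec(r, rho * r^2),
    source = vol * trapz_vec(r, rho * gamma * r^2),
    Ew = vol * trapz_vec(r, Wvol * r^2),
    Ec = vol * trapz_vec(r, rho * 0.5 * k * state$c^2 * r^2),
    diss_rearr = vol * trapz_vec(r, diss_pt * r^2),
    Q = vol * trapz_vec(r, Q_pt * r^2),
    uptake = vol * trapz_vec(r, rho * params$gamma_c * k * state$c^2 * r^2),
    gradsq = vol * trapz_vec(r, D * rho * k * (c_r / R)^2 * r^2),
    influx = 4 * pi * R^2 * D * rho[N] * k * state$c[N] * c_r[N] / R,
    Fext = external_traction(load, R, state$t),
    min_diss_pt = min(diss_pt),
    max_Q_pt = max(Q_pt),
    min_c = min(state$c),
    min_gamma = min(gamma),
    max_gamma = max(gamma),
    gamma_center = gamma[1],
    gamma_rim = gamma[N]
  )
}

#' Simulate spheroid growth
#'
#' Integrates the moving-boundary system from a stress-free initial state of
#' radius `R0` (uniform nutrient `c0`) up to `t_max`, with either the
#' compressible or the incompressible solver.
#'
#' @param params a [model_params()]
#' @param load a [boundary_load()]
#' @param R0 initial radius (micrometres)
#' @param t_max final time (days)
#' @param variant `"incompressible"` or `"compressible"`
#' @param control an [incompressible_control()] or [compressible_control()];
#'   defaults to the variant's default controls
#' @param state0 optional initial [radial_state()] overriding `R0`
#' @param verbose print progress every 1000 steps
#' @return an object of class `trajectory`: `times` and `radii` (per step),
#'   `snapshots` (sparse list of states with derived fields), `series`
#'   (per-step audit scalars), and `metadata`
#' @examples
#' \donttest{
#' p <- model_params(k = 1, eta = 1, gamma_c = 0.7, L = 65)
#' tr <- simulate_spheroid(p, boundary_load("gel", cH = 0.5, R0_gel = 20),
#'                         R0 = 20, t_max = 1,
#'                         control = incompressible_control(N = 32, dt = 0.01))
#' tail(tr$radii, 1)
#' }
#' @export
simulate_spheroid <- function(params, load, R0 = 100, t_max = 10,
                              variant = c("incompressible", "compressible"),
                              control = NULL, state0 = NULL,
                              verbose = FALSE) {
  variant <- match.arg(variant)
  if (is.null(control)) {
    control <- if (variant == "incompressible") incompressible_control()
               else compressible_control()
  }
  n_retry <- 0
  repeat {
    out <- tryCatch(
      run_trajectory(params, load, R0, t_max, variant, control, state0,
                     verbose),
      spherogrowth_instability = function(e) e
    )
    if (!inherits(out, "condition")) {
      # completed, but retry with stronger damping if the force-balance
      # residual drifted above the ceiling anywhere in the run
      drifted <- variant == "compressible" &&
        out$metadata$max_fb_residual > control$eps_fb
      if (!drifted || n_retry >= 3) return(out)
    } else if (variant != "compressible" || n_retry >= 3) {
      stop(conditionMessage(out))
    }
    n_retry <- n_retry + 1
    control <- resolve_compressible_control(control, params)
    control$beta_tilde <- control$beta_tilde * 2
    control$dt <- min(control$dt, 1 / control$beta_tilde)
    if (verbose) message(sprintf(
      "force-balance drift: retrying with beta_tilde = %g, dt = %g",
      control$beta_tilde, control$dt))
  }
}

run_trajectory <- function(params, load, R0, t_max, variant, control, state0,
                           verbose) {
  if (variant == "compressible") {
    control <- resolve_compressible_control(control, params)
  }
  if (is.null(state0)) {
    # the initial pressure carries the load applied at t = 0
    p0 <- if (variant == "incompressible") {
      pressure_from_balance(rep(1, control$N),
                            external_traction(load, R0, t = 0))
    }
    state <- radial_state(N = control$N, R = R0, p = p0)
  } else {
    state <- state0
  }
  n_steps <- max(1L, ceiling((t_max - state$t) / control$dt))
  audit_every <- if (is.null(control$audit_every)) 1L else control$audit_every
  times <- numeric(n_steps + 1)
  radii <- numeric(n_steps + 1)
  fbres <- numeric(n_steps + 1)
  series <- vector("list", n_steps + 1)
  snapshots <- list()

  times[1] <- state$t
  radii[1] <- state$R
  series[[1]] <- unlist(audit_scalars(state, params, variant, load))
  snapshots[[1]] <- list(state = state,
                         fields = derived_fields(state, params, variant))
  max_fb <- 0

  for (n in seq_len(n_steps)) {
    state <- if (variant == "incompressible") {
      step_incompressible(state, params, load, control)
    } else {
      st <- step_compressible(state, params, load, control)
      fb <- attr(st, "fb_residual")
      fbres[n + 1] <- fb
      max_fb <- max(max_fb, fb)
      if (fb > 10 * control$eps_fb) {
        cond <- structure(
          class = c("spherogrowth_instability", "error", "condition"),
          list(message = sprintf(
            paste0("force-balance residual %.3e exceeded 10 * eps_fb = %.3e ",
                   "at t = %.4g; reduce dt or increase beta_tilde"),
            fb, 10 * control$eps_fb, st$t), call = NULL))
        stop(cond)
      }
      st
    }
    times[n + 1] <- state$t
    radii[n + 1] <- state$R
    if (n %% audit_every == 0 || n == n_steps) {
      series[[n + 1]] <- unlist(audit_scalars(state, params, variant, load))
    }
    if (n %% control$snapshot_every == 0 || n == n_steps) {
      snapshots[[length(snapshots) + 1]] <-
        list(state = state, fields = derived_fields(state, params, variant))
    }
    if (verbose && n %% 1000 == 0) {
      message(sprintf("t = %.3f  R = %.4f", state$t, state$R))
    }
  }

  series <- series[!vapply(series, is.null, logical(1))]
  series_df <- as.data.frame(do.call(rbind, series))
  structure(
    list(
      times = times, radii = radii, snapshots = snapshots,
      series = series_df,
      metadata = list(
        variant = variant, params = unclass(params), load = unclass(load),
        control = unclass(control), R0 = radii[1],
        max_fb_residual = if (variant == "compressible") max_fb else NA_real_,
        package_version = as.character(utils::packageVersion("spherogrowth"))
      )
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("trajectory (%s): %d steps, t in [%.4g, %.4g] days\n",
              x$metadata$variant, n - 1, x$times[1], x$times[n]))
  cat(sprintf("  R: %.5g -> %.5g um; %d snapshots\n",
              x$radii[1], x$radii[n], length(x$snapshots)))
  if (!is.null(x$metadata$max_fb_residual) &&
      !is.na(x$metadata$max_fb_residual)) {
    cat(sprintf("  max force-balance residual: %.3e\n",
                x$metadata$max_fb_residual))
  }
  invisible(x)
}

#' Interpolated radius at arbitrary times
#' @param traj a trajectory
#' @param t times within the trajectory span
#' @return radii at `t` (linear interpolation)
#' @export
radius_at <- function(traj, t) {
  if (any(t < traj$times[1] - 1e-9) ||
      any(t > traj$times[length(traj$times)] + 1e-9)) {
    stop("requested time outside the simulated span")
  }
  stats::approx(traj$times, traj$radii, xout = t, rule = 2)$y
}
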