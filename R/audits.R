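# Thermodynamic and conservation audits.
#
# The model is built so that (i) rearrangement dissipates elastic energy
# (sigma_D : Gamma_D >= 0), (ii) the growth coupling term Q is pointwise
# non-positive because gamma carries the sign of its driving bracket, and
# (iii) mass obeys d/dt int rho dV = int rho gamma dV. The audits check
# these on simulated trajectories and on randomly sampled states.

#' Mass-conservation audit
#'
#' Compares the per-step rate of the total mass with the growth source at
#' the step's start: for the explicit-Euler time advance this is the
#' scheme's own discrete conservation statement,
#' `(M_{n+1} - M_n)/dt = S_n` up to quadrature and advection truncation.
#'
#' @param traj a trajectory from [simulate_spheroid()]
#' @return list with the per-step relative discrepancy (`rel_err`), its
#'   maximum, and the underlying series
#' @export
mass_audit <- function(traj) {
  s <- traj$series
  n <- nrow(s)
  stopifnot(n >= 3)
  dMdt <- diff(s$mass) / diff(s$t)
  src <- s$source[-n]
  scale <- pmax(abs(src), 1e-12 * max(abs(s$source), 1))
  rel <- abs(dMdt - src) / scale
  # when the source vanishes identically (eta = 0) compare against the
  # mass turnover scale instead
  dead <- abs(src) < 1e-12 * max(abs(s$mass)) / max(diff(range(s$t)), 1)
  rel[dead] <- abs(dMdt[dead] - src[dead]) * diff(range(s$t)) / max(abs(s$mass))
  list(t = s$t[-n], rel_err = rel, max_rel_err = max(rel),
       dMdt = dMdt, source = src)
}

#' Energy budget audit
#'
#' Reports, per interior time point of the trajectory's per-step series:
#' the rates of the elastic and chemical energies (centred differences),
#' the rearrangement dissipation, the growth coupling `Q`, the nutrient
#' uptake and gradient dissipation, the boundary nutrient influx, and the
#' mechanical boundary power. Asserts the pointwise signs
#' `sigma_D : Gamma_D >= 0` and `Q <= 0` (recorded per step as extrema),
#' and forms the total-energy balance defect
#' `d(Ew + Ec)/dt - surface power - influx - (Q - dissipation terms)`,
#' which vanishes up to discretization error.
#'
#' @param traj a trajectory from [simulate_spheroid()]
#' @return a data.frame with one row per interior time point and an
#'   attribute `pointwise` carrying the worst-case sign violations
#' @export
energy_audit <- function(traj) {
  s <- traj$series
  n <- nrow(s)
  stopifnot(n >= 3)
  i <- 2:(n - 1)
  ddt <- function(x) (x[i + 1] - x[i - 1]) / (s$t[i + 1] - s$t[i - 1])
  dEw <- ddt(s$Ew)
  dEc <- ddt(s$Ec)
  Rdot <- ddt(s$R)
  # surface power of the external traction: v(R) * (-Fext) * area
  surface_power <- -s$Fext[i] * Rdot * 4 * pi * s$R[i]^2
  balance_defect <- dEw + dEc - surface_power - s$influx[i] -
    (s$Q[i] - s$diss_rearr[i] - s$uptake[i] - s$gradsq[i])
  out <- data.frame(
    t = s$t[i], dEw = dEw, dEc = dEc, Q = s$Q[i],
    diss_rearr = s$diss_rearr[i], uptake = s$uptake[i],
    gradsq = s$gradsq[i], influx = s$influx[i],
    surface_power = surface_power, balance_defect = balance_defect
  )
  attr(out, "pointwise") <- list(
    min_diss = min(s$min_diss_pt),
    max_Q = max(s$max_Q_pt),
    min_c = min(s$min_c)
  )
  out
}

#' Sample the rearrangement dissipation inequality
#'
#' Draws random positive stretch pairs and evaluates the contraction of the
#' deviatoric Cauchy stress with the rearrangement rate tensor, which the
#' constitutive choice makes equal to `beta * mu * Je^(-5/3) |dev Be|^2 >= 0`.
#'
#' @param n_samples number of sampled states
#' @param params a [model_params()]
#' @param seed RNG seed
#' @param log_range stretches are drawn log-uniformly from
#'   `[1/log_range, log_range]`
#' @return vector of `sigma_D : Gamma_D` values (all non-negative)
#' @export
sample_dissipation <- function(n_samples = 1e4, params = model_params(),
                               seed = 1, log_range = 3) {
  stopifnot(params$beta > 0 || params$beta == 0)
  draws <- with_local_seed(seed, {
    matrix(exp(stats::runif(2 * n_samples, -log(log_range), log(log_range))),
           ncol = 2)
  })
  fer <- draws[, 1]
  fetheta <- draws[, 2]
  s <- cauchy_stress_radial(fer, fetheta, params)
  sN <- (s$sigma_rr + 2 * s$sigma_tt) / 3
  gd <- rearrangement_rates_radial(fer, fetheta, max(params$beta, 1))
  (s$sigma_rr - sN) * gd$Gamma_rr + 2 * (s$sigma_tt - sN) * gd$Gamma_tt
}

#' Maxwell relaxation-rate estimate
#'
#' With growth switched off and no load, a small anisotropic elastic
#' perturbation relaxes by rearrangement alone:
#' `dBe/dt = -(Gamma_D Be + Be Gamma_D)`, which linearizes to
#' `d(dev Be)/dt = -2 beta dev Be`. This routine integrates the pointwise
#' stretch dynamics from `Be = I + eps * dev` (a homogeneous state needs no
#' spatial coupling), fits the exponential decay of the deviatoric stress,
#' and returns the fitted rate, expected to equal `2 beta`.
#'
#' @param params a [model_params()] with `beta > 0`
#' @param eps perturbation amplitude (default `1e-3`; amplitudes much above
#'   `1e-2` leave the linear regime and trigger a warning)
#' @param t_end duration of the relaxation run (defaults to two relaxation
#'   times)
#' @param n_times sample count for the fit
#' @return list with `rate` (fitted), `expected = 2 beta`,
#'   `relative_error`, and the fitted series
#' @export
maxwell_limit_check <- function(params, eps = 1e-3, t_end = NULL,
                                n_times = 60) {
  if (params$beta == 0) {
    # no rearrangement: the perturbed stress is frozen
    tt <- seq(0, if (is.null(t_end)) 1 else t_end, length.out = n_times)
    f_r <- sqrt(1 + 2 * eps / 3)
    f_t <- sqrt(1 - eps / 3)
    sdev <- params$mu * (f_r * f_t^2)^(-5 / 3) * (f_r^2 - f_t^2)
    return(list(rate = 0, expected = 0, relative_error = 0, t = tt,
                sigma_dev = rep(sdev, n_times)))
  }
  if (eps > 1e-2) {
    warning("perturbation beyond the linear regime; the fitted rate will be biased")
  }
  if (is.null(t_end)) t_end <- 1 / params$beta
  # dev Be = eps * diag(2/3, -1/3, -1/3): fer^2 = 1 + 2 eps/3,
  # fetheta^2 = 1 - eps/3
  y0 <- c(fer = sqrt(1 + 2 * eps / 3), fetheta = sqrt(1 - eps / 3))
  beta <- params$beta
  derivs <- function(t, y, parms) {
    fer <- y[1]; fetheta <- y[2]
    list(c(
      -(2 * beta / 3) * (fer^2 - fetheta^2) * fer,
      -(beta / 3) * (fetheta^2 - fer^2) * fetheta
    ))
  }
  tt <- seq(0, t_end, length.out = n_times)
  sol <- deSolve::ode(y0, tt, derivs, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  sdev <- params$mu * (sol[, "fer"] * sol[, "fetheta"]^2)^(-5 / 3) *
    (sol[, "fer"]^2 - sol[, "fetheta"]^2)
  fit <- stats::lm(log(abs(sdev)) ~ tt)
  rate <- -unname(stats::coef(fit)[2])
  list(rate = rate, expected = 2 * beta,
       relative_error = abs(rate - 2 * beta) / (2 * beta),
       t = tt, sigma_dev = sdev)
}
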