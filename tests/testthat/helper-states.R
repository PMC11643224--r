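# Shared fixtures: parameter sets and randomly generated smooth states.

params_default <- function(...) {
  args <- list(K = 10, k = 1, eta = 1, gamma_c = 0.7, L = 65, beta = 0)
  args[names(list(...))] <- list(...)
  do.call(model_params, args)
}

# smooth random perturbation of the identity state on the rescaled grid,
# isotropic at the center, nutrient in (0, 1]
rand_smooth_state <- function(N = 64, R = 80, amp = 0.1) {
  r <- seq(0, 1, length.out = N)
  smooth_field <- function(a) {
    k1 <- stats::runif(1, 1, 3)
    ph <- stats::runif(1, 0, pi)
    a * (cos(k1 * pi * r + ph) * r^2 + (1 - r^2) * stats::runif(1, -1, 1))
  }
  per_t <- smooth_field(amp)
  per_r <- smooth_field(amp)
  fe_t <- 1 + per_t - per_t[1] + per_r[1]  # center isotropy
  fe_r <- 1 + per_r
  cc <- pmin(1, pmax(0.3, 1 - amp * (1 - r^2) * stats::runif(1, 0, 1)))
  radial_state(N = N, R = R, fer = fe_r, fetheta = fe_t, c = cc)
}

# random positive stretch pairs, log-uniform
rand_stretches <- function(n, range = 3) {
  matrix(exp(stats::runif(2 * n, -log(range), log(range))), ncol = 2)
}
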