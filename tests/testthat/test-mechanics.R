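# Pointwise constitutive laws, cross-checked against the full tensor forms.

# independent tensor-form evaluation of energy and stress for
# Fe = diag(fer, fetheta, fetheta)
tensor_oracle <- function(fer, fetheta, params) {
  Fe <- diag(c(fer, fetheta, fetheta))
  Be <- Fe %*% t(Fe)
  Je <- det(Fe)
  I1 <- sum(diag(Be))
  W <- 0.5 * params$mu * (Je^(-2 / 3) * I1 - 3) + 0.5 * params$K * (Je - 1)^2
  sig <- params$mu * Je^(-5 / 3) * (Be - (I1 / 3) * diag(3)) +
    params$K * (Je - 1) * diag(3)
  list(W = W, sigma_rr = sig[1, 1], sigma_tt = sig[2, 2])
}

test_that("strain energy matches the tensor form and vanishes only at rest", {
  p <- params_default(K = 10)
  expect_identical(strain_energy_density(1, 1, p), 0)
  expect_identical(strain_energy_density(1, 1, params_default(K = 1000)), 0)

  # frozen scalar evaluations
  expect_equal(strain_energy_density(1, 1.1, p), 0.2264337, tolerance = 1e-6)
  expect_equal(
    strain_energy_density(0.9^-2, 0.9, p, incompressible = TRUE),
    0.5 * (0.9^-4 + 2 * 0.81 - 3),
    tolerance = 1e-12
  )

  set.seed(11)
  st <- rand_stretches(50)
  for (i in seq_len(nrow(st))) {
    expect_equal(strain_energy_density(st[i, 1], st[i, 2], p),
                 tensor_oracle(st[i, 1], st[i, 2], p)$W, tolerance = 1e-12)
    expect_gte(strain_energy_density(st[i, 1], st[i, 2], p), 0)
  }
  expect_error(strain_energy_density(-1, 1, p), "positive")
})

test_that("Cauchy stress matches the tensor form, traceless deviator, sigma_N = K(Je-1)", {
  p <- params_default(K = 10)
  s0 <- cauchy_stress_radial(1, 1, p)
  expect_identical(c(s0$sigma_rr, s0$sigma_tt), c(0, 0))

  s <- cauchy_stress_radial(1, 1.1, p)
  or <- tensor_oracle(1, 1.1, p)
  expect_equal(s$sigma_rr, or$sigma_rr, tolerance = 1e-12)
  expect_equal(s$sigma_tt, or$sigma_tt, tolerance = 1e-12)
  expect_equal(s$sigma_rr, 1.998105, tolerance = 1e-6)
  expect_equal(s$sigma_tt, 2.150947, tolerance = 1e-6)

  set.seed(12)
  st <- rand_stretches(100)
  s <- cauchy_stress_radial(st[, 1], st[, 2], p)
  Je <- st[, 1] * st[, 2]^2
  sN <- (s$sigma_rr + 2 * s$sigma_tt) / 3
  # deviator traceless and volumetric part exact
  expect_equal((s$sigma_rr - sN) + 2 * (s$sigma_tt - sN), rep(0, 100),
               tolerance = 1e-13)
  expect_equal(sN, p$K * (Je - 1), tolerance = 1e-12)
  # stress difference identity, K-independent
  s2 <- cauchy_stress_radial(st[, 1], st[, 2], params_default(K = 500))
  expect_equal(s2$sigma_rr - s2$sigma_tt,
               Je^(-5 / 3) * (st[, 1]^2 - st[, 2]^2), tolerance = 1e-12)
})

test_that("compressible growth rate follows the feedback law", {
  p <- params_default(K = 10, k = 1, eta = 1)
  expect_equal(growth_rate_compressible(1, 1, 1, p), 0.5)
  expect_identical(growth_rate_compressible(0, 1.3, 0.8, p), 0)
  # frozen derived value at fer = 1, fetheta = 1.1
  Je <- 1.21
  W <- strain_energy_density(1, 1.1, p)
  expect_equal(growth_rate_compressible(1, 1, 1.1, p),
               0.5 / Je + 10 * 0.21 - W / Je, tolerance = 1e-12)
  expect_equal(growth_rate_compressible(1, 1, 1.1, p), 2.326088,
               tolerance = 1e-6)
  # gamma scales linearly in eta and c
  expect_equal(growth_rate_compressible(0.5, 1, 1.1, p),
               0.5 * (0.5 * 0.25 / Je + 10 * 0.21 - W / Je), tolerance = 1e-12)
})

test_that("incompressible growth rate vanishes on the zero-growth manifold and decreases in p", {
  p <- params_default(k = 1, eta = 1)
  expect_equal(growth_rate_incompressible(1, 1, 1, p), 0.5)
  expect_identical(growth_rate_incompressible(0, 0.7, 0.9, p), 0)
  # zero-growth relation: p = I1/3 - W + k c^2 / 2
  set.seed(13)
  for (f in exp(stats::runif(20, -0.3, 0.3))) {
    cc <- stats::runif(1, 0.2, 1)
    I1 <- f^-4 + 2 * f^2
    W <- 0.5 * (I1 - 3)
    p_star <- I1 / 3 - W + 0.5 * cc^2
    expect_equal(growth_rate_incompressible(cc, p_star, f, p), 0,
                 tolerance = 1e-12)
    # strictly decreasing in pressure
    expect_lt(growth_rate_incompressible(cc, p_star + 0.1, f, p), 0)
    expect_gt(growth_rate_incompressible(cc, p_star - 0.1, f, p), 0)
  }
})

test_that("rearrangement rates are traceless and dissipative", {
  g0 <- rearrangement_rates_radial(1.4, 1.4, 0.7)
  expect_identical(c(g0$Gamma_rr, g0$Gamma_tt), c(0, 0))
  g <- rearrangement_rates_radial(2, 1, 0.5)
  expect_equal(g$Gamma_rr, 1.0)
  expect_equal(g$Gamma_tt, -0.5)

  set.seed(14)
  st <- rand_stretches(200)
  p <- params_default(K = 7)
  beta <- 0.3
  g <- rearrangement_rates_radial(st[, 1], st[, 2], beta)
  expect_equal(g$Gamma_rr + 2 * g$Gamma_tt, rep(0, 200), tolerance = 1e-13)
  s <- cauchy_stress_radial(st[, 1], st[, 2], p)
  sN <- (s$sigma_rr + 2 * s$sigma_tt) / 3
  contraction <- (s$sigma_rr - sN) * g$Gamma_rr +
    2 * (s$sigma_tt - sN) * g$Gamma_tt
  expect_true(all(contraction >= 0))
  # algebraic identity: sigma_D : Gamma_D = beta mu Je^(-5/3) |dev Be|^2
  Je <- st[, 1] * st[, 2]^2
  devnorm2 <- (2 / 3) * (st[, 1]^2 - st[, 2]^2)^2
  expect_equal(contraction, beta * p$mu * Je^(-5 / 3) * devnorm2,
               tolerance = 1e-12)
})

test_that("external traction covers gel, pressure, free and release", {
  gel <- boundary_load("gel", cH = 2, R0_gel = 1)
  expect_equal(external_traction(gel, 1), 0)
  expect_equal(external_traction(gel, 2), 2.9375)
  expect_equal(external_traction(gel, 1e8), 5, tolerance = 1e-6)
  expect_error(external_traction(gel, -1), "positive")

  rel <- boundary_load("gel", cH = 2, R0_gel = 1, release_time = 5)
  expect_gt(external_traction(rel, 2, t = 4.9), 0)
  expect_identical(external_traction(rel, 2, t = 5), 0)

  expect_identical(external_traction(boundary_load("free"), 3), 0)
  expect_equal(external_traction(boundary_load("pressure", Pext = 0.4), 3), 0.4)

  # dFext/dR consistent with a finite difference
  R <- 1.7
  fd <- (external_traction(gel, R + 1e-6) - external_traction(gel, R - 1e-6)) / 2e-6
  expect_equal(spherogrowth:::external_traction_dR(gel, R), fd,
               tolerance = 1e-6)
})

test_that("derived fields obey the mass-density relation", {
  set.seed(15)
  st <- rand_smooth_state(N = 32)
  p <- params_default(K = 5)
  df <- derived_fields(st, p, "compressible")
  expect_equal(df$rho * df$Je, rep(1, 32), tolerance = 1e-13)
  expect_equal(df$sigma_N, (df$sigma_rr + 2 * df$sigma_tt) / 3,
               tolerance = 1e-13)
})
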