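# Incompressible solver: velocity quadrature, pressure reconstruction,
# stepping contracts.

test_that("velocity from growth reproduces closed-form integrals", {
  N <- 101
  r <- seq(0, 1, length.out = N)
  R <- 40
  g <- 0.8
  expect_equal(velocity_from_growth(rep(0, N), R), rep(0, N))
  # uniform gamma: v = g r R / 3 exactly (quadrature exact for linear gamma)
  expect_equal(velocity_from_growth(rep(g, N), R), g * r * R / 3,
               tolerance = 1e-13)
  expect_equal(velocity_from_growth(rep(g, N), R)[N] * 3 / R, g,
               tolerance = 1e-13)
  # quadratic gamma(s) = g s^2 (rescaled): v = g R r^3 / 5
  v <- velocity_from_growth(g * r^2, R)
  expect_lt(max(abs(v - g * R * r^3 / 5)), 1e-4 * max(abs(v)))
  # refinement: second-order accurate
  err_at <- function(N) {
    r <- seq(0, 1, length.out = N)
    max(abs(velocity_from_growth(g * r^2, R) - g * R * r^3 / 5))
  }
  expect_gte(log2(err_at(51) / err_at(101)), 1.9)
})

test_that("pressure from balance: uniform states and refinement oracle", {
  N <- 64
  expect_equal(pressure_from_balance(rep(1, N), 0), rep(1, N),
               tolerance = 1e-12)
  expect_equal(pressure_from_balance(rep(1, N), 0.3), rep(1.3, N),
               tolerance = 1e-12)
  # smooth profile: compare against a fine-grid solve restricted to the
  # coarse nodes
  f_of <- function(r) 1 - 0.05 * r^2 + 0.02 * r^3
  p_coarse <- pressure_from_balance(f_of(seq(0, 1, length.out = 65)), 0.1)
  p_fine <- pressure_from_balance(f_of(seq(0, 1, length.out = 1025)), 0.1)
  expect_equal(p_coarse, p_fine[seq(1, 1025, by = 16)], tolerance = 1e-5)
})

test_that("identity state with no growth is an exact fixed point", {
  p <- params_default(eta = 0, gamma_c = 0, K = 10)
  ctrl <- incompressible_control(N = 32, dt = 0.01)
  st <- radial_state(N = 32, R = 100, p = rep(1, 32))
  for (i in 1:100) st <- step_incompressible(st, p, boundary_load("free"), ctrl)
  drift <- max(abs(st$fetheta - 1), abs(st$fer - 1), abs(st$R - 100),
               abs(st$c - 1), abs(st$p - 1))
  expect_lt(drift, 1e-12)
})

test_that("stepping preserves incompressibility and the pressure boundary condition", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7, beta = 0.1)
  ld <- boundary_load("gel", cH = 0.5, R0_gel = 50)
  ctrl <- incompressible_control(N = 48, dt = 5e-3)
  st <- radial_state(N = 48, R = 50, p = rep(1, 48))
  for (i in 1:200) {
    st <- step_incompressible(st, p, ld, ctrl)
    expect_equal(st$fer * st$fetheta^2, rep(1, 48), tolerance = 1e-14)
  }
  Fext <- external_traction(ld, st$R, st$t)
  expect_equal(st$p[48], st$fer[48]^2 + Fext, tolerance = 1e-13)
  expect_true(all(st$c > 0 & st$c <= 1))
})

test_that("early free growth is exponential at rate eta k / 6", {
  # uniform nutrient (no uptake) keeps gamma spatially uniform, so
  # dR/dt = gamma R / 3 with gamma ~ eta k / 2 while strains stay tiny
  p <- params_default(k = 1, eta = 1, gamma_c = 0)
  tr <- simulate_spheroid(p, boundary_load("free"), R0 = 100, t_max = 0.02,
                          variant = "incompressible",
                          control = incompressible_control(N = 32, dt = 1e-4))
  R_pred <- 100 * exp(1 * 1 * 0.02 / 6)
  expect_equal(tail(tr$radii, 1), R_pred, tolerance = 1e-4)
})

test_that("volume bookkeeping: d(R^3)/dt matches the boundary velocity", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7)
  tr <- simulate_spheroid(p, boundary_load("free"), R0 = 60, t_max = 0.5,
                          variant = "incompressible",
                          control = incompressible_control(N = 32, dt = 1e-3))
  R <- tr$radii
  t <- tr$times
  n <- length(R)
  i <- 2:(n - 1)
  dR3 <- (R[i + 1]^3 - R[i - 1]^3) / (t[i + 1] - t[i - 1])
  # mass source for the incompressible tissue is rho0 * integral of gamma,
  # which the series records; 4 pi R^2 Rdot must match it
  expect_equal(dR3 * 4 * pi / 3, tr$series$source[i], tolerance = 5e-3)
})

test_that("constant pressure above k/2 shrinks the spheroid monotonically", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7)
  tr <- simulate_spheroid(p, boundary_load("pressure", Pext = 0.6), R0 = 50,
                          t_max = 3, variant = "incompressible",
                          control = incompressible_control(N = 32, dt = 2e-3))
  expect_true(all(diff(tr$radii) < 0))
})
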