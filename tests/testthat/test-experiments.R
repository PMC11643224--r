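# Fitting toolkit, synthetic data, serialization, configuration.

make_toy_traj <- function(times = seq(0, 10, by = 0.1), R0 = 50, g = 0.05) {
  # analytic exponential trajectory wrapped in the trajectory class, enough
  # for the error metric
  structure(list(times = times, radii = R0 * exp(g * times),
                 snapshots = list(), series = NULL,
                 metadata = list(variant = "toy")),
            class = "trajectory")
}

test_that("relative error metric sums |R(t_i) - R_i| / R_i", {
  tr <- make_toy_traj()
  t_obs <- c(1, 3, 5, 7.5)
  exact <- radius_dataset(t_obs, 50 * exp(0.05 * t_obs))
  expect_equal(relative_error(tr, exact), 0)

  off <- radius_dataset(seq(1, 7, by = 1), 50 * exp(0.05 * seq(1, 7, by = 1)) / 1.1)
  # R(t_i) = 1.1 R_i at 7 points
  expect_equal(relative_error(tr, off), 7 * 0.1, tolerance = 1e-12)

  # hand-summed 3-point toy: data 10% low, 5% high, exact
  t3 <- c(2, 4, 6)
  R_true <- 50 * exp(0.05 * t3)
  d3 <- radius_dataset(t3, R_true * c(0.9, 1.05, 1))
  expect_equal(relative_error(tr, d3),
               0.1 / 0.9 + 0.05 / 1.05 + 0, tolerance = 1e-12)

  expect_error(relative_error(tr, radius_dataset(c(5, 20), c(60, 70))),
               "outside")
})

test_that("AICc prefers the smaller model at equal fit and is hand-computable", {
  eq <- aicc_compare(0.5, 0.5, m1 = 4, m2 = 5, n = 12,
                     labels = c("incompressible", "compressible"))
  expect_identical(eq$preferred, "incompressible")
  same <- aicc_compare(0.3, 0.3, m1 = 4, m2 = 4, n = 12)
  expect_equal(same$delta, 0)
  # worked toy, n = 10: AICc = n log(RSS/n) + 2m + 2m(m+1)/(n-m-1)
  a1 <- 10 * log(0.8 / 10) + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1)
  a2 <- 10 * log(0.5 / 10) + 2 * 3 + 2 * 3 * 4 / (10 - 3 - 1)
  out <- aicc_compare(0.8, 0.5, 2, 3, 10)
  expect_equal(unname(out$aicc), c(a1, a2), tolerance = 1e-12)
  expect_error(aicc_compare(1, 1, 4, 5, n = 7), "too few")
})

test_that("synthetic generator is seeded, exact at zero noise, and correctly scaled", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7)
  ld <- boundary_load("gel", cH = 0.5, R0_gel = 20)
  ctrl <- incompressible_control(N = 24, dt = 0.02)
  times <- seq(0.5, 4, length.out = 8)

  ds0 <- generate_synthetic_radius_data(p, ld, times, noise_sd = 0, seed = 7,
                                        R0 = 20, control = ctrl)
  tr <- simulate_spheroid(p, ld, R0 = 20, t_max = 4, control = ctrl)
  expect_equal(ds0$radii, radius_at(tr, times), tolerance = 1e-12)

  ds_a <- generate_synthetic_radius_data(p, ld, times, noise_sd = 0.02,
                                         seed = 7, R0 = 20, control = ctrl)
  ds_b <- generate_synthetic_radius_data(p, ld, times, noise_sd = 0.02,
                                         seed = 7, R0 = 20, control = ctrl)
  expect_identical(ds_a$radii, ds_b$radii)
  ds_c <- generate_synthetic_radius_data(p, ld, times, noise_sd = 0.02,
                                         seed = 8, R0 = 20, control = ctrl)
  expect_false(identical(ds_a$radii, ds_c$radii))

  # noise scale: many draws against the shared noiseless curve
  many <- seq(0.1, 4, length.out = 400)
  ds_m <- generate_synthetic_radius_data(p, ld, many, noise_sd = 0.02,
                                         seed = 9, R0 = 20, control = ctrl)
  base <- radius_at(tr, many)
  expect_equal(stats::sd(ds_m$radii / base - 1), 0.02, tolerance = 0.25)
})

test_that("degenerate single-point data is flagged non-identifiable", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7)
  ld <- boundary_load("gel", cH = 0.5, R0_gel = 20)
  ctrl <- incompressible_control(N = 16, dt = 0.05)
  ds <- radius_dataset(2, 22)
  fit <- grid_search_fit(ds, free = list(eta = c(0.5, 2)), params = p,
                         load = ld, R0 = 20, control = ctrl,
                         n_coarse = 3, n_fine = 3, refine = 1)
  expect_true(fit$non_identifiable)
  expect_true(all(is.finite(fit$history$err)))
})

test_that("one-parameter noiseless recovery lands within a fine-grid cell", {
  p <- params_default(k = 1, eta = 0.8, gamma_c = 0.7)
  ld <- boundary_load("gel", cH = 0.5, R0_gel = 20)
  ctrl <- incompressible_control(N = 24, dt = 0.02)
  times <- seq(1, 6, length.out = 8)
  ds <- generate_synthetic_radius_data(p, ld, times, noise_sd = 0, seed = 3,
                                       R0 = 20, control = ctrl)
  fit <- grid_search_fit(ds, free = list(eta = c(0.1, 10)),
                         params = params_default(k = 1, gamma_c = 0.7),
                         load = ld, R0 = 20, control = ctrl,
                         n_coarse = 7, n_fine = 7, refine = 2)
  expect_lt(abs(fit$best[["eta"]] / 0.8 - 1), fit$fine_step[["eta"]] - 1)
  expect_true(all(fit$within10$err <= 1.1 * fit$err))
})

test_that("trajectory and dataset serialization round-trips", {
  p <- params_default(k = 1, eta = 1, gamma_c = 0.7)
  tr <- simulate_spheroid(p, boundary_load("pressure", Pext = 0.2), R0 = 40,
                          t_max = 0.2, variant = "incompressible",
                          control = incompressible_control(N = 24, dt = 0.01,
                                                           snapshot_every = 10))
  dir <- file.path(tempdir(), "traj_rt")
  write_trajectory(tr, dir)
  tr2 <- read_trajectory(dir)
  expect_equal(tr2$times, tr$times, tolerance = 1e-15)
  expect_equal(tr2$radii, tr$radii, tolerance = 1e-15)
  expect_equal(nrow(tr2$series), nrow(tr$series))
  expect_equal(tr2$series$Ew, tr$series$Ew, tolerance = 1e-15)
  expect_equal(length(tr2$snapshots), length(tr$snapshots))
  last <- length(tr$snapshots)
  expect_equal(tr2$snapshots[[last]]$state$fetheta,
               tr$snapshots[[last]]$state$fetheta, tolerance = 1e-15)
  expect_equal(tr2$metadata$params$k, 1)

  ds <- radius_dataset(c(1, 2, 3), c(10.123456789, 11, 12))
  f <- tempfile(fileext = ".csv")
  write_radius_dataset(ds, f)
  ds2 <- read_radius_dataset(f)
  expect_equal(ds2$radii, ds$radii, tolerance = 1e-15)
})

test_that("flat key = value configuration files parse into model objects", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c(
    "# spheroid in gel",
    "k = 1.5", "eta = 0.7", "gamma_c = 0.7", "L = 65", "beta = 0.05",
    "K = 30",
    "load_kind = gel", "load_cH = 0.5", "load_R0_gel = 20",
    "R0 = 20", "t_max = 5", "variant = compressible",
    "N = 48", "dt = 0.001"
  ), f)
  cfg <- read_config(f)
  expect_s3_class(cfg$params, "model_params")
  expect_equal(cfg$params$k, 1.5)
  expect_equal(cfg$params$beta, 0.05)
  expect_identical(cfg$load$kind, "gel")
  expect_equal(cfg$load$cH, 0.5)
  expect_identical(cfg$sim$variant, "compressible")
  expect_equal(cfg$control_args$N, 48)
  expect_error(read_config({
    g <- tempfile(); writeLines("nonsense line", g); g
  }), "cannot parse")
})
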