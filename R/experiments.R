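# Fitting toolkit: radius datasets, the relative-error metric, staged grid
# search, AICc model comparison, and the synthetic radius-series generator.

#' Radius-versus-time dataset
#'
#' @param times observation times (days, strictly increasing)
#' @param radii observed radii (> 0)
#' @param noise_sd optional known multiplicative noise level
#' @param provenance `"synthetic"` or `"user"`
#' @return an object of class `radius_dataset`
#' @export
radius_dataset <- function(times, radii, noise_sd = NULL,
                           provenance = c("user", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(length(times) == length(radii), all(diff(times) > 0),
            all(radii > 0))
  structure(list(times = times, radii = radii, noise_sd = noise_sd,
                 provenance = provenance),
            class = "radius_dataset")
}

#' @export
print.radius_dataset <- function(x, ...) {
  cat(sprintf("radius_dataset (%s): %d points, t in [%g, %g] days, R in [%.4g, %.4g]\n",
              x$provenance, length(x$times), min(x$times), max(x$times),
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' Relative-error goodness of fit
#'
#' `err = sum_i |R(t_i) - R_i| / R_i`, with the simulated radius linearly
#' interpolated at the observation times.
#'
#' @param traj a trajectory from [simulate_spheroid()]
#' @param data a [radius_dataset()]
#' @return the summed relative error (0 iff the curves agree at every point)
#' @export
relative_error <- function(traj, data) {
  Rt <- radius_at(traj, data$times)
  sum(abs(Rt - data$radii) / data$radii)
}

#' Synthetic radius series from known parameters
#'
#' Simulates the model and perturbs the sampled radii with multiplicative
#' Gaussian noise, `R_i = R(t_i) (1 + xi_i)`, `xi_i ~ N(0, noise_sd)`.
#' Stands in for digitized experimental radius curves so the fitting
#' pipeline can be exercised end to end with a known ground truth.
#'
#' @param params a [model_params()]
#' @param load a [boundary_load()]
#' @param sample_times observation times (days)
#' @param noise_sd multiplicative noise standard deviation (>= 0)
#' @param seed RNG seed (recorded in the dataset)
#' @param R0,variant,control forwarded to [simulate_spheroid()]
#' @return a [radius_dataset()] with `provenance = "synthetic"`
#' @export
generate_synthetic_radius_data <- function(params, load, sample_times,
                                           noise_sd = 0.02, seed = 1,
                                           R0 = 20,
                                           variant = "incompressible",
                                           control = NULL) {
  stopifnot(noise_sd >= 0)
  traj <- simulate_spheroid(params, load, R0 = R0,
                            t_max = max(sample_times), variant = variant,
                            control = control)
  Rt <- radius_at(traj, sample_times)
  xi <- with_local_seed(seed, stats::rnorm(length(sample_times), 0, noise_sd))
  ds <- radius_dataset(sample_times, Rt * (1 + xi), noise_sd = noise_sd,
                       provenance = "synthetic")
  ds$seed <- seed
  ds$truth <- list(params = unclass(params), load = unclass(load), R0 = R0)
  ds
}

# evaluate expr under a local seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Staged grid-search fit
#'
#' Minimizes the relative error over a grid of free parameters: a coarse
#' logarithmic sweep first, then successively finer local grids centred on
#' the running best (the classic coarse-then-fine strategy; additional
#' refinement stages shrink the final cell). Deterministic given the grid
#' specification. Also reports every evaluated combination within 10% of
#' the best error, as a robustness set.
#'
#' @param data a [radius_dataset()]
#' @param free named list of `c(lo, hi)` bounds (positive) for the free
#'   parameters, e.g. `list(eta = c(0.1, 10), k = c(0.1, 10))`; names must
#'   be [model_params()] fields
#' @param params baseline [model_params()] supplying the fixed parameters
#' @param load a [boundary_load()]
#' @param R0 initial radius passed to the simulator
#' @param variant solver variant
#' @param control solver controls (choose to match the data-generating
#'   resolution when recovering synthetic truth)
#' @param n_coarse points per axis in the coarse stage
#' @param n_fine points per axis in each refinement stage
#' @param refine number of refinement stages (>= 1)
#' @return list with `best` (named parameter vector), `err`, `history`
#'   (data.frame of every evaluation), `within10` (robustness set),
#'   `fine_step` (final multiplicative cell size per axis), and
#'   `non_identifiable` flag for degenerate datasets
#' @export
grid_search_fit <- function(data, free, params, load, R0 = 20,
                            variant = "incompressible", control = NULL,
                            n_coarse = 7, n_fine = 7, refine = 2) {
  stopifnot(length(free) >= 1, !is.null(names(free)),
            all(names(free) %in% names(params)))
  for (b in free) stopifnot(length(b) == 2, all(b > 0), b[1] < b[2])

  eval_grid <- function(axes) {
    grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
    errs <- rep(NA_real_, nrow(grid))
    for (i in seq_len(nrow(grid))) {
      p_try <- params
      for (nm in names(axes)) p_try[[nm]] <- grid[[nm]][i]
      errs[i] <- tryCatch({
        traj <- simulate_spheroid(p_try, load, R0 = R0,
                                  t_max = max(data$times),
                                  variant = variant, control = control)
        relative_error(traj, data)
      }, error = function(e) NA_real_)
    }
    cbind(grid, err = errs)
  }

  # stage 1: coarse logarithmic sweep of the stated bounds
  axes <- lapply(free, function(b) {
    exp(seq(log(b[1]), log(b[2]), length.out = n_coarse))
  })
  hist <- eval_grid(axes)
  if (all(is.na(hist$err))) stop("every candidate simulation failed")
  stage_step <- vapply(free, function(b) {
    (b[2] / b[1])^(1 / (n_coarse - 1))
  }, numeric(1))

  # refinement stages: span +/- one previous cell around the running best
  for (s in seq_len(refine)) {
    best <- hist[which.min(hist$err), , drop = FALSE]
    axes <- list()
    for (nm in names(free)) {
      ctr <- best[[nm]]
      axes[[nm]] <- exp(seq(log(ctr / stage_step[[nm]]),
                            log(ctr * stage_step[[nm]]),
                            length.out = n_fine))
    }
    hist <- rbind(hist, eval_grid(axes))
    stage_step <- vapply(stage_step, function(sp) {
      sp^(2 / (n_fine - 1))
    }, numeric(1))
  }

  hist <- hist[!is.na(hist$err), , drop = FALSE]
  ib <- which.min(hist$err)
  best <- unlist(hist[ib, names(free), drop = FALSE])
  within10 <- hist[hist$err <= 1.1 * hist$err[ib], , drop = FALSE]
  list(
    best = best, err = hist$err[ib], history = hist, within10 = within10,
    fine_step = stage_step,
    non_identifiable = length(data$times) < length(free) + 1
  )
}

#' AICc comparison of two model variants
#'
#' Small-sample-corrected Akaike information criterion from a Gaussian
#' likelihood proxy on the relative residuals:
#' `AICc = n log(RSS / n) + 2 m + 2 m (m + 1) / (n - m - 1)` where `RSS` is
#' the sum of squared relative residuals and `m` the number of fitted
#' parameters. Smaller is preferred; with equal fits, the variant with
#' fewer parameters wins by the penalty terms.
#'
#' @param rss1,rss2 residual sums of squares of the two variants
#' @param m1,m2 fitted parameter counts
#' @param n number of data points (must exceed `max(m1, m2) + 2`)
#' @param labels names of the two variants
#' @return list with `aicc` (named vector), `preferred`, `delta`
#'   (`aicc[2] - aicc[1]`)
#' @export
aicc_compare <- function(rss1, rss2, m1, m2, n,
                         labels = c("model1", "model2")) {
  if (n <= max(m1, m2) + 2) {
    stop("too few data points for the small-sample correction")
  }
  aicc <- function(rss, m) {
    n * log(rss / n) + 2 * m + 2 * m * (m + 1) / (n - m - 1)
  }
  a <- c(aicc(rss1, m1), aicc(rss2, m2))
  names(a) <- labels
  list(aicc = a, preferred = labels[which.min(a)],
       delta = unname(a[2] - a[1]))
}
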