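# Rescaled-grid state container and derived fields.

#' Radially-symmetric model state on the rescaled grid
#'
#' Holds the fields of the moving-boundary problem after the change of
#' variable `r' = r / R(t)`: the grid lives on `[0, 1]` and the boundary
#' radius `R` carries the geometry. `fer` and `fetheta` are the radial and
#' hoop elastic stretches, `c` the nutrient concentration and, for the
#' incompressible variant, `p` the pressure field.
#'
#' @param N number of grid nodes (>= 16)
#' @param R boundary radius (micrometres, > 0)
#' @param fer,fetheta elastic stretch fields (length `N`, default identity)
#' @param c nutrient field (default uniform `c0 = 1`)
#' @param p pressure field or `NULL` (compressible variant)
#' @param t time in days
#' @return an object of class `radial_state`
#' @examples
#' s <- radial_state(N = 64, R = 100)
#' s
#' @export
radial_state <- function(N = 64, R = 100, fer = rep(1, N),
                         fetheta = rep(1, N), c = rep(1, N), p = NULL,
                         t = 0) {
  stopifnot(N >= 16, R > 0, length(fer) == N, length(fetheta) == N,
            length(c) == N)
  if (any(fer <= 0) || any(fetheta <= 0)) stop("stretches must be positive")
  if (any(c < 0) || any(c > 1 + 1e-12)) {
    stop("nutrient concentration must lie in [0, c0 = 1]")
  }
  if (abs(fer[1] - fetheta[1]) > 1e-8 * max(1, abs(fer[1]))) {
    stop("the center node must be isotropic (fer = fetheta at r = 0)")
  }
  structure(
    list(
      r_grid = seq(0, 1, length.out = N),
      fer = fer, fetheta = fetheta, c = c, p = p, R = R, t = t
    ),
    class = "radial_state"
  )
}

#' @export
print.radial_state <- function(x, ...) {
  N <- length(x$r_grid)
  cat(sprintf("radial_state: N = %d nodes, R = %.4g um, t = %.4g days\n",
              N, x$R, x$t))
  cat(sprintf("  fer in [%.4g, %.4g], fetheta in [%.4g, %.4g], c in [%.4g, %.4g]\n",
              min(x$fer), max(x$fer), min(x$fetheta), max(x$fetheta),
              min(x$c), max(x$c)))
  if (!is.null(x$p)) cat(sprintf("  p in [%.4g, %.4g]\n", min(x$p), max(x$p)))
  invisible(x)
}

#' Fields derived from a radial state
#'
#' Computes the elastic volumetric variation `Je`, density `rho = rho0/Je`,
#' strain energy `W`, Cauchy stresses, normal stress average, and the
#' growth-rate field for either variant. For the incompressible variant the
#' stresses include the pressure (`sigma_rr = mu fer^2 - p`).
#'
#' @param state a [radial_state()]
#' @param params a [model_params()]
#' @param variant `"compressible"` or `"incompressible"`
#' @return a data.frame, one row per node, with columns `r`, `fer`,
#'   `fetheta`, `c`, `Je`, `rho`, `W`, `sigma_rr`, `sigma_tt`, `sigma_N`,
#'   `gamma` (and `p` for the incompressible variant)
#' @export
derived_fields <- function(state, params,
                           variant = c("compressible", "incompressible")) {
  variant <- match.arg(variant)
  fer <- state$fer
  fetheta <- state$fetheta
  if (variant == "compressible") {
    Je <- fer * fetheta^2
    W <- strain_energy_density(fer, fetheta, params)
    s <- cauchy_stress_radial(fer, fetheta, params)
    gamma <- growth_rate_compressible(state$c, fer, fetheta, params)
    data.frame(
      r = state$r_grid, fer = fer, fetheta = fetheta, c = state$c,
      Je = Je, rho = params$rho0 / Je, W = W,
      sigma_rr = s$sigma_rr, sigma_tt = s$sigma_tt,
      sigma_N = (s$sigma_rr + 2 * s$sigma_tt) / 3, gamma = gamma
    )
  } else {
    if (is.null(state$p)) stop("incompressible derived fields need a pressure field")
    Je <- rep(1, length(fer))
    W <- strain_energy_density(fer, fetheta, params, incompressible = TRUE)
    srr <- params$mu * fetheta^-4 - state$p
    stt <- params$mu * fetheta^2 - state$p
    gamma <- growth_rate_incompressible(state$c, state$p, fetheta, params)
    data.frame(
      r = state$r_grid, fer = fer, fetheta = fetheta, c = state$c,
      p = state$p, Je = Je, rho = rep(params$rho0, length(fer)), W = W,
      sigma_rr = srr, sigma_tt = stt, sigma_N = (srr + 2 * stt) / 3,
      gamma = gamma
    )
  }
}
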