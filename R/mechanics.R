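# Pointwise constitutive laws in radial symmetry (d = 3).
#
# The elastic state at a point is the pair of principal elastic stretches
# (fer, fetheta) of Fe = diag(fer, fetheta, fetheta); Je = fer * fetheta^2 is
# the elastic volumetric variation and rho = rho0 / Je the density.

.check_stretch <- function(fer, fetheta) {
  if (any(!is.finite(fer)) || any(!is.finite(fetheta)) ||
      any(fer <= 0) || any(fetheta <= 0)) {
    stop("elastic stretches must be positive and finite")
  }
}

#' Neo-Hookean strain energy density
#'
#' Energy per unit intermediate (stress-free grown) volume,
#' `W = mu/2 (Ibar1 - 3) + K/2 (Je - 1)^2` with
#' `Ibar1 = Je^(-2/3) (fer^2 + 2 fetheta^2)` for the compressible law, or
#' `W = mu/2 (I1 - 3)` with `fer = fetheta^-2` for the incompressible one.
#'
#' @param fer radial elastic stretch (> 0); ignored (recomputed) when
#'   `incompressible = TRUE`
#' @param fetheta hoop elastic stretch (> 0)
#' @param params a [model_params()]
#' @param incompressible if `TRUE`, use the isochoric law with
#'   `fer = fetheta^-2`
#' @return energy density, same shape as the inputs
#' @examples
#' p <- model_params(K = 10)
#' strain_energy_density(1, 1, p)            # 0 at the identity
#' strain_energy_density(1, 1.1, p)          # ~0.2264
#' @export
strain_energy_density <- function(fer, fetheta, params,
                                  incompressible = FALSE) {
  if (incompressible) fer <- fetheta^-2
  .check_stretch(fer, fetheta)
  I1 <- fer^2 + 2 * fetheta^2
  if (incompressible) {
    return(0.5 * params$mu * (I1 - 3))
  }
  Je <- fer * fetheta^2
  Ibar1 <- Je^(-2 / 3) * I1
  0.5 * params$mu * (Ibar1 - 3) + 0.5 * params$K * (Je - 1)^2
}

#' Radial and hoop Cauchy stress (compressible law)
#'
#' `sigma_rr = 2/3 mu Je^(-5/3) (fer^2 - fetheta^2) + K (Je - 1)` and
#' `sigma_tt = 1/3 mu Je^(-5/3) (fetheta^2 - fer^2) + K (Je - 1)`.
#' The deviatoric part is traceless and the normal stress average
#' `(sigma_rr + 2 sigma_tt) / 3` equals `K (Je - 1)` exactly.
#'
#' @inheritParams strain_energy_density
#' @return a list with components `sigma_rr` and `sigma_tt`
#' @examples
#' cauchy_stress_radial(1, 1.1, model_params(K = 10))
#' @export
cauchy_stress_radial <- function(fer, fetheta, params) {
  .check_stretch(fer, fetheta)
  Je <- fer * fetheta^2
  S <- Je^(-5 / 3)
  vol <- params$K * (Je - 1)
  list(
    sigma_rr = (2 / 3) * params$mu * S * (fer^2 - fetheta^2) + vol,
    sigma_tt = (1 / 3) * params$mu * S * (fetheta^2 - fer^2) + vol
  )
}

#' Chemomechanical growth rate, compressible tissue
#'
#' `gamma = eta c (k rho c^2 / 2 + K (Je - 1) - W / Je)` with
#' `rho = rho0 / Je`: growth is driven by the excess of chemical energy
#' release over the elastic energy cost, plus the normal stress average
#' `K (Je - 1)` (compression suppresses growth).
#'
#' @param c nutrient concentration (>= 0)
#' @inheritParams strain_energy_density
#' @return volumetric growth rate (1/day)
#' @examples
#' growth_rate_compressible(1, 1, 1, model_params(k = 1, eta = 1))  # eta k / 2
#' @export
growth_rate_compressible <- function(c, fer, fetheta, params) {
  .check_stretch(fer, fetheta)
  stopifnot(all(c >= 0))
  Je <- fer * fetheta^2
  rho <- params$rho0 / Je
  W <- strain_energy_density(fer, fetheta, params)
  params$eta * c *
    (0.5 * params$k * rho * c^2 + params$K * (Je - 1) - W / Je)
}

#' Chemomechanical growth rate, incompressible tissue
#'
#' `gamma = eta c (k c^2 / 2 + I1/3 - p - W)` with `I1 = fetheta^-4 +
#' 2 fetheta^2`: the normal stress average is `sigma_N = mu I1 / 3 - p`, so
#' growth vanishes exactly on the manifold `W + p - I1/3 = k c^2 / 2`, which
#' is the zero-growth relation used by the equilibrium analysis.
#'
#' @param c nutrient concentration (>= 0)
#' @param p pressure (Lagrange multiplier of incompressibility)
#' @param fetheta hoop elastic stretch
#' @param params a [model_params()]
#' @return volumetric growth rate (1/day)
#' @export
growth_rate_incompressible <- function(c, p, fetheta, params) {
  stopifnot(all(c >= 0))
  .check_stretch(fetheta^-2, fetheta)
  I1 <- fetheta^-4 + 2 * fetheta^2
  W <- 0.5 * params$mu * (I1 - 3)
  params$eta * c * (0.5 * params$k * c^2 + params$mu * I1 / 3 - p - W)
}

#' Deviatoric rearrangement rates in radial symmetry
#'
#' The deviatoric growth-rate tensor is `Gamma_D = beta (Be - tr(Be)/3 I)`,
#' so radially `Gamma_rr = 2 beta / 3 (fer^2 - fetheta^2)` and
#' `Gamma_tt = beta / 3 (fetheta^2 - fer^2)`. The trace vanishes exactly and
#' the contraction with the deviatoric stress is non-negative (rearrangement
#' dissipates elastic energy).
#'
#' @param fer radial elastic stretch
#' @param fetheta hoop elastic stretch
#' @param beta rearrangement rate (>= 0)
#' @return list with `Gamma_rr` and `Gamma_tt`
#' @export
rearrangement_rates_radial <- function(fer, fetheta, beta) {
  stopifnot(beta >= 0)
  .check_stretch(fer, fetheta)
  list(
    Gamma_rr = (2 * beta / 3) * (fer^2 - fetheta^2),
    Gamma_tt = (beta / 3) * (fetheta^2 - fer^2)
  )
}

#' Compressive external traction at the spheroid surface
#'
#' For a gel load, the traction exerted by an incompressible neo-Hookean gel
#' whose stress-free cavity radius is `R0_gel`:
#' `Fext = cH/2 (5 - R0 (R0^3 + 4 R^3) / R^4)`; it vanishes at `R = R0_gel`
#' and saturates at `5 cH / 2` for large spheroids. A released gel exerts no
#' traction after `release_time`. A pressure load returns `Pext`; a free
#' surface returns 0.
#'
#' @param load a [boundary_load()]
#' @param R current spheroid radius (> 0)
#' @param t current time in days (used for `release_time`)
#' @return compressive traction `Fext >= 0` (total radial surface stress is
#'   `-Fext`)
#' @examples
#' external_traction(boundary_load("gel", cH = 2, R0_gel = 1), R = 2)  # 2.9375
#' @export
external_traction <- function(load, R, t = 0) {
  if (any(R <= 0)) stop("radius must be positive")
  switch(load$kind,
    free = 0 * R,
    pressure = rep(load$Pext, length(R)),
    gel = {
      if (!is.null(load$release_time) && t >= load$release_time) {
        0 * R
      } else {
        R0 <- load$R0_gel
        (load$cH / 2) * (5 - R0 * (R0^3 + 4 * R^3) / R^4)
      }
    }
  )
}

# dFext/dR, needed by the damped boundary condition of the compressible
# velocity solve (the traction moves with the boundary)
external_traction_dR <- function(load, R, t = 0) {
  if (any(R <= 0)) stop("radius must be positive")
  switch(load$kind,
    free = 0 * R,
    pressure = 0 * R,
    gel = {
      if (!is.null(load$release_time) && t >= load$release_time) {
        0 * R
      } else {
        R0 <- load$R0_gel
        2 * load$cH * R0 * (1 / R^2 + R0^3 / R^5)
      }
    }
  )
}
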