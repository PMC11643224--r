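# Parameter and loading-protocol containers.

#' Constitutive and feedback parameters of the nondimensional model
#'
#' Collects every constant of the nondimensionalized growth-elasticity model.
#' Lengths are in micrometres and times in days; stresses are measured in
#' units of the tissue shear modulus, which is why `mu` is fixed at 1, and
#' the boundary nutrient concentration sets the concentration scale `c0 = 1`.
#'
#' @param K bulk modulus (nondimensional). Ignored by the incompressible
#'   solver; must be positive for the compressible one.
#' @param k chemical energy coefficient. The chemical energy density is
#'   `E_c(c) = k c^2 / 2`; `k` measures chemical energy relative to elastic
#'   energy, so small `k` means strong mechanical feedback on growth.
#' @param eta growth-rate scaling factor (1/day). The feedback prefactor is
#'   `eta * c`, i.e. proliferation responds linearly to nutrient level.
#' @param gamma_c nutrient uptake rate (1/day).
#' @param L nutrient diffusion length (micrometres); the diffusivity is
#'   `D = L^2` per day.
#' @param beta rearrangement rate (1/day). Coefficient of the deviatoric,
#'   mass-conserving part of the growth-rate tensor; it relaxes stress
#'   anisotropy like a Maxwell fluid with relaxation rate `2 * beta`.
#' @param mu shear modulus; fixed at 1 by nondimensionalization.
#' @param c0 boundary nutrient concentration; fixed at 1.
#' @param rho0 initial stress-free density; fixed at 1.
#' @return an object of class `model_params`
#' @examples
#' p <- model_params(K = 10, k = 1, eta = 1, gamma_c = 0.7, L = 65, beta = 0)
#' p
#' @export
model_params <- function(K = 10, k = 1, eta = 1, gamma_c = 0.7, L = 65,
                         beta = 0, mu = 1, c0 = 1, rho0 = 1) {
  stopifnot(
    "mu is fixed to 1 by nondimensionalization" = isTRUE(all.equal(mu, 1)),
    "c0 is fixed to 1 by nondimensionalization" = isTRUE(all.equal(c0, 1)),
    "rho0 is fixed to 1" = isTRUE(all.equal(rho0, 1)),
    K > 0, k > 0, eta >= 0, gamma_c >= 0, L > 0, beta >= 0
  )
  structure(
    list(K = K, k = k, eta = eta, gamma_c = gamma_c, L = L, beta = beta,
         mu = mu, c0 = c0, rho0 = rho0),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Nondimensional growth-elasticity parameters\n")
  cat(sprintf("  shear modulus mu       : %g (fixed)\n", x$mu))
  cat(sprintf("  bulk modulus K         : %g\n", x$K))
  cat(sprintf("  chemical coefficient k : %g\n", x$k))
  cat(sprintf("  feedback scale eta     : %g /day\n", x$eta))
  cat(sprintf("  uptake rate gamma_c    : %g /day\n", x$gamma_c))
  cat(sprintf("  diffusion length L     : %g um  (D = %g um^2/day)\n", x$L, x$L^2))
  cat(sprintf("  rearrangement beta     : %g /day\n", x$beta))
  invisible(x)
}

#' External loading protocol at the spheroid surface
#'
#' Describes the compressive traction `Fext` applied at the moving boundary.
#' Three protocols are supported: a traction-free surface (`free`), an
#' elastic gel displaced by the expanding spheroid (`gel`, with relative
#' rigidity `cH` and stress-free cavity radius `R0_gel`), and a constant
#' compressive pressure (`pressure`, e.g. an osmotic load `Pext`).
#' A gel load may additionally be released (set to zero) at `release_time`,
#' emulating gel-removal experiments.
#'
#' The convention throughout the package is compressive-positive: the total
#' radial Cauchy stress at the surface equals `-Fext`.
#'
#' @param kind one of `"free"`, `"gel"`, `"pressure"`
#' @param cH gel relative rigidity (gel only, >= 0)
#' @param R0_gel stress-free gel cavity radius (gel only, > 0)
#' @param Pext constant compressive pressure (pressure only, >= 0)
#' @param release_time optional time (days) at which a gel load is removed
#' @return an object of class `boundary_load`
#' @examples
#' boundary_load("gel", cH = 0.5, R0_gel = 20)
#' boundary_load("pressure", Pext = 0.3)
#' @export
boundary_load <- function(kind = c("free", "gel", "pressure"),
                          cH = NULL, R0_gel = NULL, Pext = NULL,
                          release_time = NULL) {
  kind <- match.arg(kind)
  if (kind == "gel") {
    stopifnot(!is.null(cH), !is.null(R0_gel), cH >= 0, R0_gel > 0)
  } else {
    if (!is.null(release_time)) {
      stop("release_time is only meaningful for a gel load")
    }
  }
  if (kind == "pressure") stopifnot(!is.null(Pext), Pext >= 0)
  if (!is.null(release_time)) stopifnot(release_time >= 0)
  structure(
    list(kind = kind, cH = cH, R0_gel = R0_gel, Pext = Pext,
         release_time = release_time),
    class = "boundary_load"
  )
}

#' @export
print.boundary_load <- function(x, ...) {
  switch(x$kind,
    free = cat("Boundary load: traction-free surface\n"),
    gel = {
      cat(sprintf("Boundary load: gel confinement, cH = %g, cavity radius = %g\n",
                  x$cH, x$R0_gel))
      if (!is.null(x$release_time)) {
        cat(sprintf("  gel released at t = %g days\n", x$release_time))
      }
    },
    pressure = cat(sprintf("Boundary load: constant pressure Pext = %g\n", x$Pext))
  )
  invisible(x)
}
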