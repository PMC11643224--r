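---
title: "Chemomechanical growth-elasticity of tumor spheroids: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemomechanical growth-elasticity of tumor spheroids: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spherogrowth)
```

This vignette explains the model the package solves, the numerical
choices behind the solvers, and the limits of what the test suite
demonstrates. It is the package's reference for *why* the code looks the
way it does; the README shows *how* to run it.

## The model

### Kinematics and elasticity

The deformation gradient of a growing tissue is decomposed
multiplicatively, `F = Fe Fg`. The growth tensor `Fg` adds (possibly
incompatible) stress-free volume at the volumetric rate
`gamma = tr(Gamma)`; the elastic tensor `Fe` restores compatibility and
responds to loads, and is the sole argument of the strain energy. Density
changes are purely elastic: `rho Je = rho0` with `Je = det Fe`, so mass
balance reads `d/dt int rho dV = int rho gamma dV`.

The tissue is isotropic neo-Hookean,

`W(Fe) = mu/2 (Ibar1 - 3) + K/2 (Je - 1)^2`, `Ibar1 = Je^(-2/3) tr(Be)`,

with Cauchy stress
`sigma = mu Je^(-5/3) (Be - tr(Be)/3 I) + K (Je - 1) I`. The volumetric
part of the stress is exactly `sigma_N = K (Je - 1)`; this identity is
asserted in the tests. The incompressible variant replaces the `K` term
by a pressure field `p` (then `sigma_N = mu tr(Be)/3 - p`).

### Energy-dissipative growth and rearrangement

A growth factor ("nutrient") with boundary concentration `c0 = 1`
diffuses and is consumed; its chemical energy density is
`E_c = k c^2 / 2`. Demanding that the growth trajectory dissipate the
total elastic + chemical energy leads to

* the growth-rate law
  `gamma = eta c (k rho c^2 / 2 + sigma_N - W/Je)` — growth is driven by
  the chemical energy release and penalized by compressive normal stress
  and stored elastic energy. The associated energy coupling density
  `Q = -gamma * (driving bracket) = -gamma^2 / (eta c)` is non-positive
  by construction, which the audits verify pointwise;
* the deviatoric rearrangement rate
  `Gamma_D = beta (Be - tr(Be)/3 I)`, which is traceless
  (mass-conserving) and makes `sigma_D : Gamma_D = beta mu Je^(-5/3)
  |dev Be|^2 >= 0`: rearrangement only ever relaxes stress anisotropy.
  Linearized around the identity with no growth it gives
  `d(dev Be)/dt = -2 beta dev Be`, i.e. a Maxwell fluid with relaxation
  rate `2 beta`; `maxwell_limit_check()` recovers this rate numerically
  and the acceptance suite requires agreement within 1%.

### Parameters

All quantities are nondimensional: stresses in units of the shear modulus
(`mu = 1`), concentrations in units of the boundary value (`c0 = 1`),
lengths in micrometres, times in days.

| parameter | meaning | default | why |
|---|---|---|---|
| `K` | bulk modulus | 10 | weakly compressible tissue; `K -> Inf` approaches the incompressible variant |
| `k` | chemical energy coefficient | 1 | sets feedback strength; the pressure existence threshold is `k/2` |
| `eta` | growth-rate scale (1/day) | 1 | free-growth volumetric rate is `eta k / 2`, giving day-scale doubling as in spheroid cultures |
| `gamma_c` | nutrient uptake (1/day) | 0.7 | with `L = 65` gives a visible center-to-rim nutrient drop at radii of order 100 um |
| `L` | diffusion length (um) | 65 | `D = L^2` per day; same pairing as the uptake default |
| `beta` | rearrangement rate (1/day) | 0 | purely elastic tissue unless rearrangement is being studied |

The `gamma_c = 0.7`, `L = 65` pairing is the regime in which the
equilibrium analyses of the package are exercised; the remaining defaults
are round numbers at the natural scale of the nondimensional model.

## Radial solvers

Both solvers work on the rescaled radius `r' = r / R(t)` in `[0, 1]`
(`N` uniform nodes), so the moving boundary becomes a fixed endpoint and
`R(t)` a scalar unknown advanced by the boundary velocity. The advective
frame velocity is `v_tilde = (v - r' Rdot)/R`; it vanishes at both ends.
Advection of the stretches and the nutrient uses a second-order upwind
stencil whose side follows the sign of `v_tilde` nodewise; other spatial
derivatives use five-point (fourth-order) stencils with one-sided rows at
the ends. Time integration of the stretches and `R` is explicit Euler, as
the structure of the damped velocity equation below assumes; the audits
quantify the resulting first-order-in-time conservation error.

Loading is compressive-positive throughout: the total radial stress at
the surface is `-Fext`, with `Fext` from the gel formula, the constant
pressure, or zero. (The alternative sign convention would make the
pressure boundary condition and the equilibrium existence bound
internally inconsistent, so this one is forced.)

### Center regularization

`r = 0` is a symmetry point, not an equation row. The center node is kept
isotropic (`fer = fetheta`), `v(0) = 0` is pinned, `2/r` terms use their
symmetric limits (`v/r -> v'(0)`, `sigma_s/r -> sigma_s'(0)` with
`sigma_s(0) = 0`), and the nutrient Laplacian at the origin is `3 c''(0)`
via a ghost-node argument.

### Incompressible stepping

With `Je = 1`, `fer = fetheta^-2` and only `fetheta` is evolved. Each
step: (i) pressure from integrating the radial force balance inward from
`p(1) = fer(1)^2 + Fext` — this makes the surface condition hold exactly
on every stored state; (ii) `gamma` from the feedback law; (iii) velocity
from incompressibility, `v = (R/r^2) int_0^r gamma s^2 ds`. Because the
pressure depends only on the strains and the traction, this sweep is
already the fixed point of the coupled pressure–growth–velocity system;
the iteration loop in `solve_vpg_incompressible()` re-evaluates the
cheap stages and checks that the update norm is below `tol`, so a
nonlinear fallback solver is never reachable and none is implemented.

The velocity integral uses a moment quadrature that is exact for
piecewise-linear `gamma`. This matters: the plain trapezoid applied to
`gamma s^2` overestimates the first-cell integral by 50%, which enters
`v/r` at the second node undamped and seeds a grid-scale checkerboard
that central difference stencils cannot see (they annihilate the
alternating mode). With the moment quadrature the near-center fields stay
smooth to rounding.

### Compressible stepping: the damped velocity surrogate

Mechanical equilibrium `div sigma = 0` does not contain the velocity, so
the velocity is revealed by time-differentiating the force balance and
damping its residual `G = d(sigma_rr)/dr + (2/r)(sigma_rr - sigma_tt)`:

`dG/dt + beta_tilde G = 0.`

Substituting the strain evolution laws and the constitutive derivatives
turns this into a linear equation
`a1 v + a2 v' + a3 v'' + a8 v(1) + a4 = 0` in the bulk plus a damped
traction condition at the surface. The `a8 v(1)` term is the nonlocal
footprint of the moving rescaled frame (the frame velocity contains
`Rdot = v(1)`); a gel load also contributes `dFext/dR * v(1)` to the
boundary row. The assembled coefficients are gated by a
finite-difference-in-time oracle (`surrogate_residual_check()`): the
state is advanced by a tiny step with the computed velocity and the
observed decay rate of `G` must match `beta_tilde` within 1%.

The damping cannot beat the physics: at quasi-steady tracking the
residual floor is (rate of change of the constraint)/`beta_tilde`, and
stress rates scale with `K`. The default damping therefore scales as
`beta_tilde = max(1e3, 10 K)` per day, with the step tied to stability of
the explicitly damped recursion (`dt <= 1/beta_tilde`) and an automatic
doubling retry if the residual still drifts above the ceiling
`eps_fb = 1e-4` (as a fraction of the stress scale). The monitored
residual covers the rows the discrete system imposes — the bulk equation
on interior nodes and the traction defect `|sigma_rr(1) + Fext|`; the
center row is the symmetry closure `v(0) = 0`, where the one-sided
evaluation of the analytically-vanishing `G(0)` is pure truncation noise.

### Nutrient transport

Uptake and diffusion are implicit (tridiagonal solve), advection explicit
second-order upwind — a first-order operator splitting using the frame
velocity of the same step. The compressible variant uses the conservative
face-flux form with arithmetic-mean face weights
`(r_i^2 rho_i + r_{i+1}^2 rho_{i+1})/2`; the incompressible variant uses
the non-conservative central form `D/R^2 (c'' + 2 c'/r)`, whose error
constant for the steady profile is markedly smaller (about 1e-7 max-abs
at `N = 512` against the closed form
`c = (R/r) sinh(r/l) / sinh(R/l)`, `l = L / sqrt(gamma_c)`). Both are
second-order in space and obey a discrete maximum principle under the
advective step-size restriction, so `0 < c <= c0` throughout.

## Equilibrium shooting

For the incompressible model without rearrangement, equilibria satisfy
"zero growth everywhere" plus force balance. Eliminating the pressure
gives a scalar ODE for `fetheta(r)` driven by the nutrient gradient; the
surface value must satisfy
`Fext = k/2 - W - (2/3)(fetheta^-4 - fetheta^2)`, whose right side lies
in `[0, k/2]` for `fetheta` in `(0, 1]` — hence a constant pressure
above `k/2` admits no equilibrium, while a gel always meets the curve at
some finite radius because its traction falls with shrinking `R`.

The integration direction was a genuinely open design choice. Shooting
*inward* from the surface is natural on paper but numerically hopeless:
linearizing about the isotropic center shows the homogeneous error mode
grows like `(R/r)^3`, amplifying surface-value error by ~1e9 at
`r = 1e-3 R`, so the center residual becomes a step function of `R`.
The package instead integrates *outward* from the regular center
expansion `fetheta = 1 - k c(0)^2 r^2 / (60 mu l^2)`, along which the
same mode decays; the residual — required minus applied surface traction
— is then a smooth function of `R`, scanned on a log grid and bisected.
Converged profiles satisfy the surface relation to ~1e-11 and the
center-versus-surface pressure consistency to ~1e-9, and the equilibrium
radius agrees with the long-time limit of the dynamic solver to a few
parts in 1e4.

## Fitting toolkit and synthetic data

The goodness of fit is the summed relative radius error
`err = sum_i |R(t_i) - R_i| / R_i`. The grid search runs a coarse
logarithmic sweep of the stated bounds and then refinement stages, each a
local log-grid spanning one previous cell around the running best; the
default of two refinements after a 7-point coarse stage ends at ~9%
multiplicative cells. (The two-stage coarse-then-fine strategy
generalizes naturally to staged refinement; a single fine stage at the
same final resolution would cost far more simulations.) Model variants
are compared by the small-sample Akaike criterion
`AICc = n log(RSS/n) + 2m + 2m(m+1)/(n - m - 1)` on a Gaussian proxy for
the relative residuals.

The synthetic generator simulates the model and applies multiplicative
Gaussian noise `R_i = R(t_i)(1 + xi_i)`, `xi ~ N(0, sd)`, reproducibly
by seed. Its default scenario — gel confinement `cH = 0.5` around a
20 um spheroid, 20 samples over 20 days, 2% noise — covers both the
growth transient (which identifies `eta`) and the confined plateau
(which identifies `k` through the equilibrium size). What it emulates is
the *sampling* of radius curves, not real measurement pathologies:
noise is independent, homoscedastic and unbiased, the model is exactly
the generator, and initial radius and load are known. Parameter-recovery
tests passing therefore shows the pipeline is consistent and the design
identifiable at this noise level — not that the model fits any real
spheroid, and not robustness to model misspecification.

## Problem sizes and tolerances

The shipped tests run at desk scale, chosen so each check's signal is
well above its discretization floor: grids of 32–64 nodes, horizons of
0.25–40 days, steps of 1e-3–2e-2 days (the compressible solver's step
follows `1/beta_tilde`). Key tolerances: machine-level (1e-12) drift for
exact fixed points and algebraic identities; 1e-3 relative for the mass
audit (first order in time); 1e-4 stress-fraction for the force-balance
ceiling; 1% for the surrogate decay rate and the Maxwell rate; 1e-6
max-abs for the nutrient steady state at `N = 512`. The energy budget is
audited once the boundary layer created by the uniform initial nutrient
has resolved; across that startup the centred-difference energy rates are
not meaningful.

## Known limitations

* Strictly radial geometry; no non-spherical perturbations or multi-D.
* Explicit first-order time integration; conservation audits, not exact
  discrete conservation.
* The compressible solver's damping makes force balance a controlled
  approximation with a `K`-dependent cost; very stiff tissues are
  expensive.
* Equilibrium analysis covers only the incompressible,
  rearrangement-free case; `beta > 0` steady states (which carry internal
  flow) are reached dynamically.
* One chemical species with linear uptake and constant diffusivity.
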