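#' Uniaxial permittivity moments from principal refractive indices
#'
#' A uniaxial material is characterized by the ordinary index `n_o`
#' (polarization perpendicular to the symmetry axis) and extraordinary index
#' `n_e` (parallel). The mean and differential relative permittivity are
#' `eps_r = (n_e^2 + n_o^2)/2` and `delta_eps = (n_e^2 - n_o^2)/2`; the optic
#' sign of the material is `sign(delta_eps)`.
#'
#' @param n_o,n_e ordinary / extraordinary refractive indices (`> 0`),
#'   vectorized.
#' @return list with `eps_mean` and `delta_eps`.
#' @seealso [indices_from_moments()] for the inverse map.
#' @examples
#' moments_from_indices(1.525, 1.55)
#' @export
moments_from_indices <- function(n_o, n_e) {
  if (any(n_o <= 0) || any(n_e <= 0))
    stop("refractive indices must be positive")
  list(eps_mean = (n_e^2 + n_o^2) / 2, delta_eps = (n_e^2 - n_o^2) / 2)
}

#' Principal refractive indices from permittivity moments
#'
#' @param eps_mean mean relative permittivity (`> |delta_eps|`).
#' @param delta_eps signed differential permittivity.
#' @return list with `n_o`, `n_e`.
#' @export
indices_from_moments <- function(eps_mean, delta_eps) {
  if (any(eps_mean <= abs(delta_eps)))
    stop("eps_mean must exceed |delta_eps| for real indices")
  list(n_o = sqrt(eps_mean - delta_eps), n_e = sqrt(eps_mean + delta_eps))
}

# Fold an axis parameterization into the canonical ranges
# omega in [0, pi), theta in [0, pi], using (omega, theta) ~ (omega+pi, pi-theta).
fold_axis <- function(omega, theta) {
  omega <- omega %% (2 * pi)
  flip <- omega >= pi
  omega[flip] <- omega[flip] - pi
  theta[flip] <- pi - theta[flip]
  list(omega = omega, theta = theta)
}

#' Per-voxel uniaxial permittivity field
#'
#' Container for the four per-voxel parameters of a uniaxial permittivity
#' tensor: mean permittivity `eps_mean` (dimensionless, `> 0`), signed
#' differential permittivity `delta_eps` (`|delta_eps| < eps_mean`), in-plane
#' orientation `omega` in `[0, pi)` (axis, counterclockwise from +x) and
#' inclination `theta` in `[0, pi]` (polar angle from +z). Orientations are
#' axes, not vectors: `(omega, theta)` and `(omega + pi, pi - theta)`
#' describe the same axis and are folded to the canonical range.
#'
#' @param eps_mean,delta_eps,omega,theta arrays of identical dimension (or
#'   scalars, recycled against `shape`).
#' @param shape optional `(nz, ny, nx)` used when all inputs are scalars.
#' @return `pti_uniaxial_field` object with array fields.
#' @export
uniaxial_field <- function(eps_mean, delta_eps = 0, omega = 0, theta = pi / 2,
                           shape = NULL) {
  if (is.null(shape)) {
    shape <- if (!is.null(dim(eps_mean))) dim(eps_mean) else length(eps_mean)
  }
  bc <- function(x) if (is.null(dim(x)) && length(x) == 1L)
    array(x, shape) else array(as.numeric(x), shape)
  eps_mean <- bc(eps_mean); delta_eps <- bc(delta_eps)
  omega <- bc(omega); theta <- bc(theta)
  if (any(eps_mean <= 0)) stop("eps_mean must be positive everywhere")
  if (any(abs(delta_eps) >= eps_mean))
    stop("|delta_eps| must be < eps_mean everywhere")
  f <- fold_axis(omega, theta)
  out <- list(eps_mean = eps_mean, delta_eps = delta_eps,
              omega = f$omega, theta = pmin(pmax(f$theta, 0), pi))
  class(out) <- "pti_uniaxial_field"
  out
}

#' @export
print.pti_uniaxial_field <- function(x, ...) {
  d <- dim(x$eps_mean)
  cat(sprintf("pti_uniaxial_field: %s voxels, eps_mean in [%.4g, %.4g], |delta_eps| max %.4g\n",
              paste(d, collapse = " x "), min(x$eps_mean), max(x$eps_mean),
              max(abs(x$delta_eps))))
  invisible(x)
}

#' Uniaxial permittivity tensor of a single voxel
#'
#' Builds the symmetric 3x3 relative permittivity tensor
#' `eps = eps_mean*I + delta_eps*(2*a a^T - ... )` parameterized by the
#' symmetry axis `a = (sin(theta)cos(omega), sin(theta)sin(omega),
#' cos(theta))`. Its eigenvalues are `{n_o^2, n_o^2, n_e^2}` with the
#' non-degenerate eigenvector along `a`; the trace is
#' `3*eps_mean - delta_eps`.
#'
#' @param eps_mean,delta_eps,omega,theta scalar voxel parameters.
#' @return 3x3 symmetric numeric matrix (axes ordered x, y, z).
#' @export
permittivity_matrix <- function(eps_mean, delta_eps, omega, theta) {
  st <- sin(theta); ct <- cos(theta)
  m <- matrix(c(
    eps_mean - delta_eps * (ct^2 - st^2 * cos(2 * omega)),
    delta_eps * st^2 * sin(2 * omega),
    delta_eps * sin(2 * theta) * cos(omega),
    delta_eps * st^2 * sin(2 * omega),
    eps_mean - delta_eps * (ct^2 + st^2 * cos(2 * omega)),
    delta_eps * sin(2 * theta) * sin(omega),
    delta_eps * sin(2 * theta) * cos(omega),
    delta_eps * sin(2 * theta) * sin(omega),
    eps_mean + delta_eps * cos(2 * theta)), 3, 3)
  m
}

#' Scattering potential tensor components of a uniaxial field
#'
#' Decomposes the relative permittivity contrast against the medium into the
#' seven scalar component volumes of the scattering potential tensor
#' `f = k0^2 (eps - eps_rm I)`:
#' \describe{
#'   \item{f_0r (+ i f_0i)}{isotropic part `k0^2 (eps_r - eps_rm -
#'     delta_eps cos^2 theta)`; `f_0i` carries absorption and is zero for the
#'     transparent specimens modelled here.}
#'   \item{f_1c, f_1s}{`k0^2 delta_eps sin^2(theta) {cos, sin}(2 omega)`}
#'   \item{f_2c, f_2s}{`k0^2 delta_eps sin(2 theta) {cos, sin}(omega)`}
#'   \item{f_3}{`k0^2 delta_eps (3 cos^2 theta - 1)`}
#' }
#' Units are um^-2. The 3x3 tensor is reassembled as
#' `[[f0+f1c, f1s, f2c], [f1s, f0-f1c, f2s], [f2c, f2s, f0+f3]]`.
#'
#' @param field a [uniaxial_field()].
#' @param grid a [pti_grid()] whose shape matches the field.
#' @return `pti_scattering_potential`: list of seven volumes
#'   `f_0r, f_0i, f_1c, f_1s, f_2c, f_2s, f_3` plus the `grid`.
#' @export
scattering_potential_from_material <- function(field, grid) {
  stopifnot(inherits(field, "pti_uniaxial_field"), inherits(grid, "pti_grid"))
  if (!identical(dim(field$eps_mean), as.integer(grid$shape)))
    stop("field and grid shapes disagree")
  if (max(abs(field$eps_mean - grid$eps_rm)) > 0.1 ||
      max(abs(field$delta_eps)) > 0.05)
    warning("permittivity contrast exceeds the weak-scattering regime in ",
            "which the single-scattering model is accurate")
  k2 <- grid$k0^2
  de <- field$delta_eps; th <- field$theta; om <- field$omega
  st2 <- sin(th)^2
  sp <- list(
    f_0r = k2 * (field$eps_mean - grid$eps_rm - de * cos(th)^2),
    f_0i = array(0, dim(de)),
    f_1c = k2 * de * st2 * cos(2 * om),
    f_1s = k2 * de * st2 * sin(2 * om),
    f_2c = k2 * de * sin(2 * th) * cos(om),
    f_2s = k2 * de * sin(2 * th) * sin(om),
    f_3  = k2 * de * (3 * cos(th)^2 - 1),
    grid = grid)
  class(sp) <- "pti_scattering_potential"
  sp
}

sp_component_names <- c("f_0r", "f_0i", "f_1c", "f_1s", "f_2c", "f_2s", "f_3")

# Empty (all-zero) scattering potential on a grid
scattering_potential_zero <- function(grid) {
  z <- array(0, grid$shape)
  sp <- list(f_0r = z, f_0i = z, f_1c = z, f_1s = z, f_2c = z, f_2s = z,
             f_3 = z, grid = grid)
  class(sp) <- "pti_scattering_potential"
  sp
}

#' @export
print.pti_scattering_potential <- function(x, ...) {
  cat(sprintf("pti_scattering_potential: %s voxels, max|f_0r| = %.4g um^-2, max anisotropic = %.4g um^-2\n",
              paste(dim(x$f_0r), collapse = " x "), max(abs(x$f_0r)),
              max(abs(x$f_1c), abs(x$f_1s), abs(x$f_2c), abs(x$f_2s), abs(x$f_3))))
  invisible(x)
}

#' Extract uniaxial material parameters from scattering-potential components
#'
#' Closed-form algebraic inversion of [scattering_potential_from_material()]
#' under an assumed optic sign. With `g_l = f_l / k0^2`, set
#' `a1 = hypot(g_1c, g_1s) = |delta_eps| sin^2 theta` and
#' `a2 = hypot(g_2c, g_2s) = |delta_eps| |sin 2 theta|`; then
#' `theta = atan2(2 a1, a2)` (in `[0, pi/2]`),
#' `|delta_eps| = sqrt(a1^2 + (a2/2)^2) / sin theta` when `sin theta`
#' is resolvable, else `delta_eps = g_3 / (3 cos^2 theta - 1)` on the
#' `theta = 0` branch. The in-plane axis is
#' `omega = atan2(s*g_1s, s*g_1c)/2` for assumed sign `s`, with the pi
#' ambiguity of `2*omega` resolved by aligning `(cos omega, sin omega)`
#' with `s*(g_2c, g_2s)` where `a2` is resolvable; the result is folded to
#' the canonical `omega in [0, pi)`, `theta in [0, pi]` axis range.
#' The mean permittivity contrast is `g_0r + delta_eps cos^2 theta`.
#'
#' Degenerate voxels (all anisotropic components below `tol`) return
#' `delta_eps = 0`, `omega = 0`, `theta = pi/2`.
#'
#' @param sp a `pti_scattering_potential`.
#' @param sign_assumption `+1` (positive uniaxial) or `-1` (negative).
#' @param grid grid of the components (defaults to `sp$grid`).
#' @param tol degeneracy tolerance on `g`-scale components.
#' @return a [uniaxial_field()] whose `eps_mean` holds the CONTRAST
#'   `eps_r - eps_rm` (not absolute permittivity), with signed `delta_eps`.
#' @export
material_from_scattering_potential <- function(sp, sign_assumption = +1,
                                               grid = sp$grid, tol = 1e-8) {
  s <- sign(sign_assumption)
  if (s == 0) stop("sign_assumption must be +1 or -1")
  k2 <- grid$k0^2
  g0 <- sp$f_0r / k2
  g1c <- sp$f_1c / k2; g1s <- sp$f_1s / k2
  g2c <- sp$f_2c / k2; g2s <- sp$f_2s / k2
  g3 <- sp$f_3 / k2
  a1 <- sqrt(g1c^2 + g1s^2)
  a2 <- sqrt(g2c^2 + g2s^2)

  # main branch: axis away from z, theta from the harmonic magnitudes
  theta <- atan2(2 * a1, a2)            # in [0, pi/2]
  st <- sin(theta)
  de_abs <- array(0, dim(g0))
  ok <- st > tol
  de_abs[ok] <- sqrt(a1[ok]^2 + (a2[ok] / 2)^2) / st[ok]
  delta_eps <- s * de_abs
  theta[!ok] <- 0

  omega <- 0.5 * atan2(s * g1s, s * g1c)     # in (-pi/2, pi/2]
  # resolve the pi ambiguity of the axis with the first-harmonic components
  use2 <- a2 > tol
  dot <- cos(omega) * (s * g2c) + sin(omega) * (s * g2s)
  flip <- use2 & (dot < 0)
  omega[flip] <- omega[flip] + pi
  # negative omegas are refolded (with the matching theta flip) by fold_axis

  # z-axis branch: theta = 0, only f_3 = 2 k0^2 delta_eps survives (signed)
  de_z <- g3 / 2

  # pick per voxel by recomposition residual over the five anisotropic
  # components (exact in both regimes; robust where the harmonics are
  # numerically degenerate, e.g. coarse-grained fields with axes along z)
  st2 <- sin(theta)^2; s2t <- sin(2 * theta)
  r_main <- (delta_eps * st2 * cos(2 * omega) - g1c)^2 +
    (delta_eps * st2 * sin(2 * omega) - g1s)^2 +
    (delta_eps * s2t * cos(omega) - g2c)^2 +
    (delta_eps * s2t * sin(omega) - g2s)^2 +
    (delta_eps * (3 * cos(theta)^2 - 1) - g3)^2
  r_z <- g1c^2 + g1s^2 + g2c^2 + g2s^2 + (2 * de_z - g3)^2
  # take the z-axis branch only where it is a near-exact fit (the main
  # branch remains the estimator for voxels no branch can fit exactly,
  # e.g. under a mismatched optic-sign assumption)
  pow <- g1c^2 + g1s^2 + g2c^2 + g2s^2 + g3^2
  usez <- r_z < r_main & r_z <= 1e-2 * pow
  delta_eps[usez] <- de_z[usez]
  theta[usez] <- 0
  omega[usez] <- 0

  # fully isotropic voxels: defined fallback
  iso <- (a1 <= tol) & (a2 <= tol) & (abs(g3) <= tol)
  omega[iso] <- 0
  theta[iso] <- pi / 2
  delta_eps[iso] <- 0

  f <- fold_axis(omega, theta)
  eps_contrast <- g0 + delta_eps * cos(f$theta)^2

  out <- list(eps_mean = eps_contrast, delta_eps = delta_eps,
              omega = f$omega, theta = f$theta)
  class(out) <- "pti_uniaxial_field"
  out
}

#' Out-of-plane tilt of the symmetry axis
#'
#' Converts inclination `theta` (polar angle from the imaging axis z) to the
#' absolute tilt out of the focal plane, `|theta - pi/2|`.
#'
#' @param theta inclination in radians, in `[0, pi]` (vectorized).
#' @return tilt in `[0, pi/2]`.
#' @examples
#' out_of_plane_tilt(pi / 2) # in-plane axis -> 0
#' @export
out_of_plane_tilt <- function(theta) {
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  abs(theta - pi / 2)
}
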