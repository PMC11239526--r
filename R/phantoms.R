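# Synthetic specimens with exact ground truth. All generators are
# deterministic (given their arguments and seed) and return a
# pti_uniaxial_field whose parameters are also the ground-truth maps.

#' Star (spoke) target with rotating birefringent wedges
#'
#' A disk or annulus in the focal plane divided into `n_wedges` equal
#' angular wedges; within each wedge the permittivity is constant and the
#' symmetry axis is uniform. The axis rotates from wedge to wedge in steps
#' of `360/n_wedges` degrees. For `sign = +1` the axis lies along the spoke
#' direction (positive uniaxial, lipid-like); for `sign = -1` it is
#' orthogonal to the spokes in-plane (negative uniaxial, written-glass
#' convention). An optional inclination sweep tilts the axis of successive
#' wedges from in-plane toward the imaging axis, exercising 3D orientation.
#'
#' @param grid a [pti_grid()].
#' @param n_wedges number of wedges (`>= 2`), default 8.
#' @param r_inner,r_outer annulus radii in um (`0 <= r_inner < r_outer`).
#' @param thickness_um axial extent of the target.
#' @param n_o,n_e ordinary/extraordinary indices of the wedge material.
#' @param sign `+1` or `-1`, see above. With `n_e < n_o` pass the indices
#'   swapped and keep `sign` consistent with `sign(n_e^2 - n_o^2)`.
#' @param inclination_sweep if `TRUE`, wedge axes additionally sweep the
#'   inclination from 90 (in-plane) to 30 degrees across wedges.
#' @return a [uniaxial_field()]; background voxels are medium
#'   (`eps_mean = eps_rm`, `delta_eps = 0`). The wedge mask is attached as
#'   attribute `"mask"`, wedge index map as `"wedge"`.
#' @export
star_target <- function(grid, n_wedges = 8, r_inner = 0, r_outer = NULL,
                        thickness_um = NULL, n_o = 1.525, n_e = 1.55,
                        sign = +1, inclination_sweep = FALSE) {
  stopifnot(inherits(grid, "pti_grid"))
  if (n_wedges < 2) stop("n_wedges must be >= 2")
  co <- grid_coords(grid)
  if (is.null(r_outer))
    r_outer <- 0.4 * min(grid$shape[2] * grid$spacing[2],
                         grid$shape[3] * grid$spacing[3])
  if (r_inner >= r_outer) stop("need r_inner < r_outer")
  if (is.null(thickness_um)) thickness_um <- 4 * grid$spacing[1]
  mo <- moments_from_indices(n_o, n_e)
  if (sign(mo$delta_eps) != sign(sign) && mo$delta_eps != 0)
    warning("sign disagrees with sign(n_e^2 - n_o^2)")

  r2 <- outer(co$y^2, co$x^2, "+")
  ang <- atan2(outer(co$y, rep(1, grid$shape[3])),
               outer(rep(1, grid$shape[2]), co$x)) %% (2 * pi)
  step <- 2 * pi / n_wedges
  wedge <- floor(ang / step)                      # 0 .. n_wedges-1
  inplane <- r2 >= r_inner^2 & r2 <= r_outer^2
  zmask <- abs(co$z) <= thickness_um / 2
  mask <- outer(zmask, inplane) > 0
  wedge3 <- outer(rep(1L, grid$shape[1]), wedge)

  # axis per wedge: spoke direction (wedge centre angle) or orthogonal
  centers <- (wedge3 + 0.5) * step
  om <- centers + (if (sign < 0) pi / 2 else 0)
  th <- array(pi / 2, grid$shape)
  if (inclination_sweep) {
    fr <- (wedge3 %% n_wedges) / max(n_wedges - 1, 1)
    th <- (pi / 2) - fr * (pi / 3)               # 90 deg down to 30 deg
  }
  eps <- array(grid$eps_rm, grid$shape)
  de <- array(0, grid$shape)
  omega <- array(0, grid$shape)
  theta <- array(pi / 2, grid$shape)
  eps[mask] <- mo$eps_mean
  de[mask] <- mo$delta_eps
  omega[mask] <- om[mask]
  theta[mask] <- th[mask]
  out <- uniaxial_field(eps, de, omega, theta)
  attr(out, "mask") <- mask
  attr(out, "wedge") <- wedge3
  attr(out, "wedge_step_deg") <- 360 / n_wedges
  out
}

#' Spherical bead phantom
#'
#' Hard-voxelized sphere (voxel centre inside the radius) of diameter
#' `diameter_um`, refractive index `n_bead` in a medium `n_medium`
#' (which may differ from the grid's immersion index), with optional uniform
#' uniaxial anisotropy `delta_eps` at a fixed 3D axis orientation.
#'
#' @param grid a [pti_grid()].
#' @param diameter_um bead diameter (must fit in the grid and span
#'   `>= 2` voxels).
#' @param n_bead isotropic index of the bead (mean permittivity
#'   `n_bead^2 + |delta_eps|` adjustments are not applied: `eps_mean =
#'   n_bead^2` inside).
#' @param n_medium background index (defaults to the grid medium).
#' @param delta_eps signed differential permittivity inside the bead.
#' @param axis_omega,axis_theta axis orientation of the anisotropy
#'   (radians).
#' @param center_um `(z, y, x)` centre offset in um.
#' @return a [uniaxial_field()] with attribute `"mask"`.
#' @export
bead_phantom <- function(grid, diameter_um, n_bead = 1.59, n_medium = NULL,
                         delta_eps = 0, axis_omega = 0, axis_theta = pi / 2,
                         center_um = c(0, 0, 0)) {
  stopifnot(inherits(grid, "pti_grid"))
  if (is.null(n_medium)) n_medium <- grid$medium_index
  rad <- diameter_um / 2
  co <- grid_coords(grid)
  if (diameter_um < 2 * min(grid$spacing))
    stop("bead must span at least 2 voxels")
  ext <- grid$shape * grid$spacing
  if (any(diameter_um > ext)) stop("bead exceeds the grid")
  dz2 <- (co$z - center_um[1])^2
  dy2 <- (co$y - center_um[2])^2
  dx2 <- (co$x - center_um[3])^2
  r2 <- outer(dz2, outer(dy2, dx2, "+"), "+")
  mask <- r2 <= rad^2
  eps <- array(n_medium^2, grid$shape)
  de <- array(0, grid$shape)
  omega <- array(0, grid$shape)
  theta <- array(pi / 2, grid$shape)
  eps[mask] <- n_bead^2
  de[mask] <- delta_eps
  omega[mask] <- axis_omega
  theta[mask] <- axis_theta
  out <- uniaxial_field(eps, de, omega, theta)
  attr(out, "mask") <- mask
  out
}

#' Cylindrical membrane (tube) phantom
#'
#' A tube along the z axis whose shell voxels are positive uniaxial with the
#' symmetry axis along the local surface normal (ordered lipid-bilayer
#' convention); lumen and outside are isotropic medium. At native resolution
#' the shell is positive uniaxial normal to the membrane; averaged below the
#' tube diameter the ensemble tensor is negative uniaxial with its axis
#' along the tube.
#'
#' @param grid a [pti_grid()].
#' @param radius_um mid-shell radius.
#' @param shell_thickness_um shell thickness.
#' @param eps_shell mean permittivity of shell voxels (defaults to medium
#'   permittivity so only anisotropy distinguishes the shell).
#' @param lipid_delta_eps positive differential permittivity of the shell.
#' @return a [uniaxial_field()] with attribute `"mask"` (shell voxels).
#' @export
tube_phantom <- function(grid, radius_um, shell_thickness_um,
                         lipid_delta_eps = 0.01, eps_shell = NULL) {
  stopifnot(inherits(grid, "pti_grid"))
  if (lipid_delta_eps <= 0) stop("lipid_delta_eps must be positive")
  co <- grid_coords(grid)
  rmax <- radius_um + shell_thickness_um / 2
  if (rmax > 0.5 * min(grid$shape[2] * grid$spacing[2],
                       grid$shape[3] * grid$spacing[3]))
    stop("shell does not fit inside the grid")
  if (is.null(eps_shell)) eps_shell <- grid$eps_rm + 2 * lipid_delta_eps
  r <- sqrt(outer(co$y^2, co$x^2, "+"))
  shell2d <- abs(r - radius_um) <= shell_thickness_um / 2
  phi <- atan2(outer(co$y, rep(1, grid$shape[3])),
               outer(rep(1, grid$shape[2]), co$x))
  mask <- outer(rep(TRUE, grid$shape[1]), shell2d) > 0
  omega2d <- phi %% pi
  eps <- array(grid$eps_rm, grid$shape)
  de <- array(0, grid$shape)
  omega <- array(0, grid$shape)
  theta <- array(pi / 2, grid$shape)
  eps[mask] <- eps_shell
  de[mask] <- lipid_delta_eps
  om3 <- outer(rep(1, grid$shape[1]), omega2d)
  omega[mask] <- om3[mask]
  # radial normal is in-plane: theta stays pi/2
  out <- uniaxial_field(eps, de, omega, theta)
  attr(out, "mask") <- mask
  out
}
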