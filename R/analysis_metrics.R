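# Post-reconstruction metrology and spatio-angular analysis.

#' Theoretical point-spread-function widths of a single lens
#'
#' Standard diffraction benchmarks: lateral FWHM `0.5 lambda / NA` and
#' axial FWHM `2 lambda / NA^2`. For a 532-nm, 1.4-NA system these evaluate
#' to 190 nm and 543 nm.
#'
#' @param wavelength_um free-space wavelength (um).
#' @param na numerical aperture.
#' @return list with `lateral_um` and `axial_um`.
#' @export
theoretical_psf_fwhm <- function(wavelength_um, na) {
  if (wavelength_um <= 0 || na <= 0) stop("need positive wavelength and NA")
  list(lateral_um = 0.5 * wavelength_um / na,
       axial_um = 2 * wavelength_um / na^2)
}

#' PSF full width at half maximum from a bead profile
#'
#' Least-squares Gaussian fit (offset + amplitude + centre + width) to a 1D
#' intensity trace through a bead image, followed by quadrature
#' deconvolution of the physical bead size:
#' `FWHM_psf = sqrt(FWHM_fit^2 - d_bead^2)` (the bead is approximated by a
#' Gaussian of equal FWHM).
#'
#' @param profile numeric intensity trace with a single dominant peak.
#' @param coords sample positions (um); defaults to unit spacing indices.
#' @param bead_diameter_um physical bead diameter deconvolved from the fit.
#' @return list with `fwhm_psf`, `fwhm_fit`, `center`, and the fit object.
#'   Errors if the fit does not converge or the fitted width does not exceed
#'   the bead size.
#' @export
fwhm_from_bead <- function(profile, coords = NULL, bead_diameter_um = 0) {
  if (is.null(coords)) coords <- seq_along(profile) - 1
  if (length(profile) != length(coords)) stop("profile/coords length mismatch")
  i0 <- which.max(profile)
  base <- min(profile)
  amp0 <- profile[i0] - base
  if (amp0 <= 0) stop("profile has no peak")
  halfmax <- base + amp0 / 2
  above <- which(profile >= halfmax)
  w0 <- max(diff(range(coords[above])), diff(range(coords)) / 20)
  s0 <- w0 / 2.3548
  obj <- function(p) {
    mdl <- p[1] + p[2] * exp(-(coords - p[3])^2 / (2 * p[4]^2))
    sum((profile - mdl)^2)
  }
  fit <- stats::optim(c(base, amp0, coords[i0], s0), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0) stop("Gaussian fit did not converge")
  sigma <- abs(fit$par[4])
  fwhm_fit <- 2 * sqrt(2 * log(2)) * sigma
  if (fwhm_fit <= bead_diameter_um)
    stop(sprintf("fitted width %.4g um does not exceed the bead size %.4g um",
                 fwhm_fit, bead_diameter_um))
  list(fwhm_psf = sqrt(fwhm_fit^2 - bead_diameter_um^2),
       fwhm_fit = fwhm_fit, center = fit$par[3], fit = fit)
}

# central-difference gradients with physical spacing (periodic boundaries)
gradient3 <- function(a, spacing) {
  sh <- function(v, k, dimn) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dim(v)[dimn]
    idx[[dimn]] <- c((1 + k):n, 1:k)[1:n] # circular shift by k
    do.call(`[`, c(list(v), idx))
  }
  list(gz = (sh(a, 1, 1) - sh(a, dim(a)[1] - 1, 1)) / (2 * spacing[1]),
       gy = (sh(a, 1, 2) - sh(a, dim(a)[2] - 1, 2)) / (2 * spacing[2]),
       gx = (sh(a, 1, 3) - sh(a, dim(a)[3] - 1, 3)) / (2 * spacing[3]))
}

# closed-form eigen-decomposition over voxels of a symmetric 3x3 tensor
# field given as six volumes; returns the eigenvector of the smallest (or
# largest) eigenvalue and the eigenvalues (sorted decreasing) as vectors.
batch_eigen3 <- function(xx, yy, zz, xy, xz, yz, which = c("smallest", "largest")) {
  which <- match.arg(which)
  n <- length(xx)
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ev <- matrix(q, n, 3)
  nz <- p > 1e-30
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    ev <- cbind(e1, e2, e3)
  }
  lam <- if (which == "smallest") ev[, 3] else ev[, 1]
  # eigenvector for lam via cross products of (A - lam I) rows
  r1 <- cbind(xx - lam, xy, xz)
  r2 <- cbind(xy, yy - lam, yz)
  r3 <- cbind(xz, yz, zz - lam)
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c1 <- cr(r1, r2); c2 <- cr(r1, r3); c3 <- cr(r2, r3)
  n1 <- rowSums(c1^2); n2 <- rowSums(c2^2); n3 <- rowSums(c3^2)
  best <- pmax(n1, n2, n3)
  v <- c1
  use2 <- n2 == best; v[use2, ] <- c2[use2, ]
  use3 <- n3 == best; v[use3, ] <- c3[use3, ]
  nv <- sqrt(rowSums(v^2))
  deg <- nv < 1e-30
  v <- v / pmax(nv, 1e-300)
  v[deg, ] <- rep(c(0, 0, 1), each = sum(deg))
  list(vec = v, values = ev, degenerate = deg)
}

#' Structure-tensor 3D orientation of a scalar volume
#'
#' Smoothed outer product of intensity gradients; the structure-parallel
#' axis is the eigenvector of the smallest eigenvalue. Coherence in `[0,1]`
#' is `(lam1 - lam3)/(lam1 + lam2 + lam3)` (0 for isotropic neighborhoods).
#'
#' @param volume numeric array `(nz, ny, nx)`.
#' @param grid a [pti_grid()] (used for spacing).
#' @param sigma_gradient Gaussian pre-smoothing (um) before gradients.
#' @param sigma_window Gaussian window (um) for tensor averaging.
#' @return list of arrays `omega` `[0, pi)`, `theta` `[0, pi]`, `coherence`.
#' @export
structure_tensor_orientation <- function(volume, grid, sigma_gradient = 0,
                                         sigma_window = 0.5) {
  stopifnot(inherits(grid, "pti_grid"))
  v <- volume
  if (sigma_gradient > 0) v <- gaussian_filter3(v, sigma_gradient, grid)
  g <- gradient3(v, grid$spacing)
  sm <- function(a) if (sigma_window > 0) gaussian_filter3(a, sigma_window, grid) else a
  Jxx <- sm(g$gx * g$gx); Jyy <- sm(g$gy * g$gy); Jzz <- sm(g$gz * g$gz)
  Jxy <- sm(g$gx * g$gy); Jxz <- sm(g$gx * g$gz); Jyz <- sm(g$gy * g$gz)
  eig <- batch_eigen3(as.vector(Jxx), as.vector(Jyy), as.vector(Jzz),
                      as.vector(Jxy), as.vector(Jxz), as.vector(Jyz),
                      which = "smallest")
  vx <- eig$vec[, 1]; vy <- eig$vec[, 2]; vz <- eig$vec[, 3]
  theta <- acos(pmin(pmax(vz, -1), 1))
  omega <- atan2(vy, vx)
  f <- fold_axis(omega, theta)
  tr <- eig$values[, 1] + eig$values[, 2] + eig$values[, 3]
  coh <- (eig$values[, 1] - eig$values[, 3]) / pmax(tr, 1e-300)
  coh[tr <= 1e-300] <- 0
  list(omega = array(f$omega, dim(volume)),
       theta = array(f$theta, dim(volume)),
       coherence = array(pmin(pmax(coh, 0), 1), dim(volume)))
}

#' Polar histogram of 3D orientations
#'
#' Mass-conserving 2D histogram over in-plane orientation `omega`
#' (azimuth bins on `[0, pi)`) and inclination `theta` (radial bins on
#' `[0, pi]` folded to `[0, pi/2]` tilt-from-plane if `fold_theta`), with
#' per-voxel weights (typically differential permittivity).
#'
#' @param omega,theta orientation arrays (radians).
#' @param weights non-negative weights, same shape (default 1).
#' @param n_omega,n_theta bin counts.
#' @param mask optional logical array restricting the histogram.
#' @param fold_theta fold `theta` about `pi/2` (axis symmetry view).
#' @return `pti_orientation_histogram`: `counts` matrix
#'   `(n_omega x n_theta)`, bin edges, `total_mass`.
#' @export
orientation_histogram <- function(omega, theta, weights = NULL,
                                  n_omega = 36, n_theta = 9, mask = NULL,
                                  fold_theta = TRUE) {
  if (is.null(weights)) weights <- array(1, dim(omega))
  stopifnot(identical(dim(omega), dim(theta)),
            identical(dim(omega), dim(weights)))
  sel <- if (is.null(mask)) rep(TRUE, length(omega)) else as.vector(mask)
  om <- as.vector(omega)[sel] %% pi
  th <- as.vector(theta)[sel]
  w <- as.vector(weights)[sel]
  if (fold_theta) th <- pi / 2 - abs(th - pi / 2)  # -> [0, pi/2], pi/2 = in-plane
  tmax <- if (fold_theta) pi / 2 else pi
  oe <- seq(0, pi, length.out = n_omega + 1)
  te <- seq(0, tmax, length.out = n_theta + 1)
  oi <- pmin(pmax(findInterval(om, oe, rightmost.closed = TRUE), 1), n_omega)
  ti <- pmin(pmax(findInterval(th, te, rightmost.closed = TRUE), 1), n_theta)
  counts <- matrix(0, n_omega, n_theta)
  acc <- tapply(w, list(factor(oi, levels = 1:n_omega),
                        factor(ti, levels = 1:n_theta)), sum)
  acc[is.na(acc)] <- 0
  counts[] <- acc
  structure(list(counts = counts, omega_edges = oe, theta_edges = te,
                 total_mass = sum(w), folded = fold_theta),
            class = "pti_orientation_histogram")
}

#' Multi-scale coarse graining of the permittivity tensor
#'
#' Gaussian low-pass filters each of the seven scattering-potential
#' component volumes to the target resolution, then extracts material
#' properties voxel-by-voxel (filter-then-extract order is definitional:
#' tensors average; extracted angles do not). The optic-sign branch per
#' voxel is chosen as the one whose recomposed components better reproduce
#' the filtered components.
#'
#' @param sp a `pti_scattering_potential`.
#' @param target_resolution_um desired resolution (Gaussian FWHM, um); must
#'   be at least the native voxel size.
#' @param grid grid (defaults to `sp$grid`).
#' @return a `pti_uniaxial_field` (contrast convention) with attribute
#'   `"sign"` (chosen per-voxel optic sign) and `"sp"` (filtered components).
#' @export
lowpass_material <- function(sp, target_resolution_um, grid = sp$grid) {
  if (target_resolution_um < max(grid$spacing))
    stop("target resolution must be coarser than the native voxel size")
  sigma <- target_resolution_um / 2.3548
  spf <- sp
  for (l in sp_component_names)
    spf[[l]] <- gaussian_filter3(sp[[l]], sigma, grid)
  props <- extract_properties(spf, grid)
  # residual of each branch against the filtered anisotropic components
  resid <- function(field) {
    r <- recompose_sp(field, grid)
    (r$f_1c - spf$f_1c)^2 + (r$f_1s - spf$f_1s)^2 +
      (r$f_2c - spf$f_2c)^2 + (r$f_2s - spf$f_2s)^2 + (r$f_3 - spf$f_3)^2
  }
  plus_better <- resid(props$plus) <= resid(props$minus)
  pick <- function(a, b) { a[!plus_better] <- b[!plus_better]; a }
  out <- list(eps_mean = pick(props$plus$eps_mean, props$minus$eps_mean),
              delta_eps = pick(props$plus$delta_eps, props$minus$delta_eps),
              omega = pick(props$plus$omega, props$minus$omega),
              theta = pick(props$plus$theta, props$minus$theta))
  class(out) <- "pti_uniaxial_field"
  attr(out, "sign") <- ifelse(plus_better, 1, -1)
  attr(out, "sp") <- spf
  out
}

#' Orientation-continuity weight map
#'
#' Local concordance of the axis field: the largest eigenvalue
#' `lambda_max` of the windowed orientation second-moment tensor
#' `mean(a a^T)` (axes `a`, not vectors), rescaled to
#' `(3 lambda_max - 1)/2` in `[0, 1]`. Locally uniform orientations give 1;
#' isotropic (fast-varying) orientations approach 0. Used to suppress edge
#' birefringence, whose orientation varies rapidly at material interfaces.
#'
#' @param omega,theta orientation arrays (radians).
#' @param window_vox cubic window half-width in voxels (`>= 1`).
#' @param weights optional non-negative per-voxel weights.
#' @return array of weights in `[0, 1]`.
#' @export
orientation_continuity_weight <- function(omega, theta, window_vox = 2,
                                          weights = NULL) {
  stopifnot(identical(dim(omega), dim(theta)), window_vox >= 1)
  ax <- sin(theta) * cos(omega)
  ay <- sin(theta) * sin(omega)
  az <- cos(theta)
  if (is.null(weights)) {
    f <- function(a) box_filter3(a, window_vox)
  } else {
    wn <- pmax(box_filter3(weights, window_vox), 1e-300)
    f <- function(a) box_filter3(a * weights, window_vox) / wn
  }
  mxx <- f(ax * ax); myy <- f(ay * ay); mzz <- f(az * az)
  mxy <- f(ax * ay); mxz <- f(ax * az); myz <- f(ay * az)
  eig <- batch_eigen3(as.vector(mxx), as.vector(myy), as.vector(mzz),
                      as.vector(mxy), as.vector(mxz), as.vector(myz),
                      which = "largest")
  lmax <- eig$values[, 1]
  w <- (3 * lmax - 1) / 2
  array(pmin(pmax(w, 0), 1), dim(omega))
}

#' Projected retardance (prior-method equivalent 2D readout)
#'
#' Converts a 3D differential-permittivity reconstruction into the
#' z-projected retardance a 2D polarization microscope would report:
#' `rho(x, y) = (pi / (lambda0 n_m)) * sum_z |delta_eps| sin^2(theta) dz`
#' (radians), using the thin-retarder linearization
#' `delta_n ~ delta_eps / (2 n_m)`.
#'
#' @param result a `pti_result` (or any list with `diff_permittivity` and
#'   `theta` arrays).
#' @param grid a [pti_grid()] (defaults to `result$grid`).
#' @return matrix `(ny, nx)` of projected retardance in radians.
#' @export
project_retardance <- function(result, grid = result$grid) {
  de <- result$diff_permittivity
  th <- result$theta
  stopifnot(length(dim(de)) == 3)
  proj <- apply(de * sin(th)^2, c(2, 3), sum) * grid$spacing[1]
  (pi / (grid$wavelength_um * grid$medium_index)) * proj
}
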