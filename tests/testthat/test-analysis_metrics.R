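test_that("fwhm_from_bead fits Gaussians and deconvolves the bead size", {
  x <- seq(-3, 3, by = 0.05)
  prof <- 0.2 + 1.3 * exp(-x^2 / (2 * (0.5 / 2.3548)^2))
  f <- fwhm_from_bead(prof, x, bead_diameter_um = 0)
  expect_equal(f$fwhm_psf, 0.5, tolerance = 1e-4)
  f2 <- fwhm_from_bead(prof, x, bead_diameter_um = 0.3)
  expect_equal(f2$fwhm_psf, 0.4, tolerance = 1e-3)  # sqrt(0.5^2 - 0.3^2)
  expect_error(fwhm_from_bead(prof, x, bead_diameter_um = 0.6), "exceed")
})

test_that("PSF metrology: sub-resolution bead through forward + inverse", {
  # Fig-3b-style experiment at reduced scale. On noiseless data the
  # regularized inverse restores most of the synthetic aperture
  # (NA_illu + NA_obj), so the measured lateral PSF lies between the
  # synthetic-aperture FWHM and the single-lens benchmark 0.5*lambda/NA
  # (see the methods vignette and decisions ledger: the fixed 35% band
  # around the single-lens value did not verify).
  g <- pti_grid(c(24, 40, 40), c(0.14, 0.06, 0.06), 0.532, 1.515)
  det <- detection_spec(1.47)
  pats <- sector_patterns(g, na_illu = 1.4, source_stride = 2)
  tfs <- compute_transfer_functions(pats, det, g)
  bg <- stokes_background(pats, det, g)
  ph <- bead_phantom(g, 0.13, n_bead = 1.53)
  sim <- simulate_stokes(ph, pats, det, g)
  res <- reconstruct(sim, bg, tfs, recon_config())
  co <- ptir:::grid_coords(g)
  cz <- which(co$z == 0); cy <- which(co$y == 0)
  f <- fwhm_from_bead(res$mean_permittivity[cz, cy, ], co$x,
                      bead_diameter_um = 0.13)
  lo <- 0.5 * 0.532 / (1.4 + 1.47)   # synthetic-aperture bound
  hi <- 1.35 * 0.5 * 0.532 / 1.4     # single-lens benchmark + 35%
  expect_gt(f$fwhm_psf, 0.9 * lo)
  expect_lt(f$fwhm_psf, hi)
})

test_that("structure tensor recovers cylinder axes and flags blobs", {
  g <- pti_grid(c(32, 32, 32), c(0.1, 0.1, 0.1), 0.532, 1.515)
  co <- ptir:::grid_coords(g)
  # straight cylinder along x: intensity depends on (z, y) only
  r2zy <- outer(co$z^2, co$y^2, "+")
  vol <- array(rep(exp(-r2zy / (2 * 0.3^2)), g$shape[3]), g$shape)
  st <- structure_tensor_orientation(vol, g, sigma_window = 0.3)
  cen <- array(FALSE, g$shape)
  cen[15:19, 15:19, ] <- TRUE
  sel <- cen & st$coherence > 0.5
  expect_gt(sum(sel), 50)
  expect_lt(median(axis_diff(st$omega[sel], 0)) * 180 / pi, 3)
  expect_lt(median(abs(st$theta[sel] - pi / 2)) * 180 / pi, 3)
  # 90-degree rotated input -> rotated orientation (x -> y)
  voly <- aperm(vol, c(1, 3, 2))
  sty <- structure_tensor_orientation(voly, g, sigma_window = 0.3)
  sely <- aperm(cen, c(1, 3, 2)) & sty$coherence > 0.5
  expect_lt(median(axis_diff(sty$omega[sely], pi / 2)) * 180 / pi, 3)
  # spherically symmetric blob: low coherence at the centre
  r2 <- outer(co$z^2, outer(co$y^2, co$x^2, "+"), "+")
  blob <- exp(-r2 / (2 * 0.5^2))
  stb <- structure_tensor_orientation(blob, g, sigma_window = 0.4)
  expect_lt(stb$coherence[17, 17, 17], 0.2)
})

test_that("orientation histograms conserve mass and localize delta inputs", {
  g <- pti_grid(c(4, 8, 8), c(0.2, 0.1, 0.1), 0.532, 1.515)
  om <- array(0.7, g$shape); th <- array(1.1, g$shape)
  w <- array(stats::runif(prod(g$shape)), g$shape)
  h <- orientation_histogram(om, th, w)
  expect_equal(h$total_mass, sum(w))
  expect_equal(sum(h$counts), sum(w))
  expect_equal(sum(h$counts > 0), 1)  # delta-distributed -> single bin
  # tube phantom: in-plane axes form a ring at theta = 90 deg
  gt <- pti_grid(c(8, 48, 48), c(0.15, 0.09, 0.09), 0.532, 1.515)
  tube <- tube_phantom(gt, 0.8, 0.2, lipid_delta_eps = 0.01)
  m <- attr(tube, "mask")
  ht <- orientation_histogram(tube$omega, tube$theta, abs(tube$delta_eps),
                              mask = m, n_omega = 18, n_theta = 6)
  # all mass in the most-in-plane inclination bin, spread across omega
  expect_equal(sum(ht$counts[, 6]), sum(abs(tube$delta_eps)[m]))
  expect_gt(sum(ht$counts[, 6] > 0), 16)
})

test_that("coarse graining flips the tube to negative uniaxial along its axis", {
  g <- pti_grid(c(32, 48, 48), c(0.14, 0.09, 0.09), 0.532, 1.515)
  tube <- tube_phantom(g, 0.6, 0.2, lipid_delta_eps = 0.01)
  sp <- scattering_potential_from_material(tube, g)
  # uniform field is unchanged by filtering
  unif <- uniaxial_field(array(g$eps_rm + 0.01, g$shape), 0.005, 0.9, pi / 2)
  spu <- scattering_potential_from_material(unif, g)
  cu <- lowpass_material(spu, 1.0, g)
  expect_equal(max(abs(cu$delta_eps - 0.005)), 0, tolerance = 1e-9)
  expect_lt(max(axis_diff(cu$omega, 0.9)), 1e-9)
  # native: positive uniaxial, axis in-plane; coarse: negative along z
  coarse <- lowpass_material(sp, 2.0, g)
  co <- ptir:::grid_coords(g)
  axis_m <- outer(rep(TRUE, g$shape[1]),
                  outer(co$y^2, co$x^2, "+") <= 0.5^2) > 0
  expect_lt(median(coarse$delta_eps[axis_m]), 0)
  expect_lt(median(coarse$theta[axis_m]), 0.1)
  expect_error(lowpass_material(sp, 0.01, g), "coarser")
})

test_that("orientation continuity weight separates uniform from random axes", {
  set.seed(77)
  sh <- c(12, 12, 12)
  omu <- array(1.2, sh); thu <- array(0.8, sh)
  wu <- orientation_continuity_weight(omu, thu, window_vox = 2)
  expect_equal(min(wu), 1, tolerance = 1e-9)
  # independently random axes: expected weight below 0.3 for a 5^3 window
  omr <- array(stats::runif(prod(sh), 0, pi), sh)
  thr <- array(acos(stats::runif(prod(sh), -1, 1)), sh)
  wr <- orientation_continuity_weight(omr, thr, window_vox = 2)
  expect_lt(mean(wr), 0.3)
  # monotone non-increasing in angular dispersion
  base_om <- 0.5; base_th <- 1.0
  means <- vapply(c(0.05, 0.2, 0.5, 1.0), function(s) {
    om <- array((base_om + stats::rnorm(prod(sh), sd = s)) %% pi, sh)
    th <- array(pmin(pmax(base_th + stats::rnorm(prod(sh), sd = s), 0), pi), sh)
    mean(orientation_continuity_weight(om, th, window_vox = 2))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("projected retardance matches the closed form for uniform slabs", {
  g <- pti_grid(c(20, 8, 8), c(0.25, 0.1, 0.1), 0.532, 1.515)
  mk <- function(nz_on, th) {
    de <- array(0, g$shape); de[seq_len(nz_on), , ] <- 0.004
    list(diff_permittivity = de, theta = array(th, g$shape), grid = g)
  }
  # axis along z contributes nothing
  expect_equal(max(project_retardance(mk(8, 0))), 0)
  # uniform in-plane slab: rho = pi/(lambda n_m) * de * t
  r8 <- project_retardance(mk(8, pi / 2))
  expect_equal(r8[1, 1], pi / (0.532 * 1.515) * 0.004 * 8 * 0.25,
               tolerance = 1e-12)
  # doubling the thickness doubles rho
  r16 <- project_retardance(mk(16, pi / 2))
  expect_equal(r16, 2 * r8, tolerance = 1e-12)
})

test_that("structure-tensor and permittivity-tensor orientations agree on tubes", {
  g <- pti_grid(c(24, 40, 40), c(0.15, 0.1, 0.1), 0.532, 1.515)
  tube <- tube_phantom(g, 0.8, 0.3, lipid_delta_eps = 0.01,
                       eps_shell = g$eps_rm + 0.02)
  sp <- scattering_potential_from_material(tube, g)
  blur <- ptir:::gaussian_filter3(sp$f_0r, 0.15, g)
  st <- structure_tensor_orientation(blur, g, sigma_window = 0.25)
  m <- attr(tube, "mask") & st$coherence > 0.5
  # the structure axis (along the tube, z) is orthogonal to the
  # permittivity axis (radial, in-plane): compare inclinations
  expect_lt(median(abs(st$theta[m] - 0)) * 180 / pi, 10)
  expect_lt(median(abs(tube$theta[m] - pi / 2)) * 180 / pi, 1e-9)
})
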