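test_that("permittivity moments and indices convert both ways", {
  m <- moments_from_indices(1.525, 1.55)
  expect_equal(m$eps_mean, 2.3640625)
  expect_equal(m$delta_eps, 0.0384375)
  expect_equal(moments_from_indices(1.33, 1.33),
               list(eps_mean = 1.33^2, delta_eps = 0))
  expect_equal(moments_from_indices(1, 1), list(eps_mean = 1, delta_eps = 0))
  back <- indices_from_moments(m$eps_mean, m$delta_eps)
  expect_equal(back$n_o, 1.525)
  expect_equal(back$n_e, 1.55)
  expect_error(moments_from_indices(-1, 1.5), "positive")
  expect_error(indices_from_moments(0.01, 0.02), "exceed")
})

test_that("permittivity matrix has uniaxial eigenstructure", {
  # forced forms
  m0 <- permittivity_matrix(2.36, 0.04, 0.77, 0)
  expect_equal(m0, diag(c(2.32, 2.32, 2.40)))
  mx <- permittivity_matrix(2.36, 0.04, 0, pi / 2)
  expect_equal(mx, diag(c(2.40, 2.32, 2.32)))
  set.seed(11)
  for (k in 1:200) {
    eps <- runif(1, 1.8, 2.6); de <- runif(1, -0.1, 0.1)
    om <- runif(1, 0, pi); th <- runif(1, 0, pi)
    M <- permittivity_matrix(eps, de, om, th)
    expect_equal(M, t(M))
    expect_equal(sum(diag(M)), 3 * eps - de, tolerance = 1e-12)
    ev <- eigen(M, symmetric = TRUE)
    vals <- sort(ev$values)
    no2 <- eps - de; ne2 <- eps + de
    expect_equal(vals, sort(c(no2, no2, ne2)), tolerance = 1e-12)
    # non-degenerate eigenvector aligns with the symmetry axis (up to sign)
    if (abs(de) > 1e-6) {
      i <- which.min(abs(ev$values - ne2))
      axis <- c(sin(th) * cos(om), sin(th) * sin(om), cos(th))
      expect_gt(abs(sum(ev$vectors[, i] * axis)), 1 - 1e-9)
    }
  }
})

test_that("scattering potential components satisfy the defining formulas", {
  g <- pti_grid(c(1, 1, 3), c(0.2, 0.1, 0.1), 0.532, 1.58)
  # axis along z: only f_3 = 2 k0^2 delta_eps among the anisotropic terms
  fz <- uniaxial_field(array(2.55, c(1, 1, 3)), 0.02, 0, 0)
  spz <- scattering_potential_from_material(fz, g)
  expect_equal(max(abs(spz$f_1c)), 0)
  expect_equal(max(abs(spz$f_1s)), 0)
  expect_equal(max(abs(spz$f_2c)), 0)
  expect_equal(max(abs(spz$f_2s)), 0)
  expect_equal(spz$f_3[1], 2 * g$k0^2 * 0.02)
  # magic inclination zeroes f_3
  fm <- uniaxial_field(array(2.55, c(1, 1, 3)), 0.02, 0.3, acos(1 / sqrt(3)))
  spm <- scattering_potential_from_material(fm, g)
  expect_lt(max(abs(spm$f_3)), 1e-12)
  # isotropic contrast: f_0r = k0^2 (n^2 - n_m^2), Fig-2b-like indices
  fi <- uniaxial_field(array(1.59^2, c(1, 1, 3)), 0, 0, pi / 2)
  spi <- scattering_potential_from_material(fi, g)
  expect_equal(spi$f_0r[1], g$k0^2 * (1.59^2 - 1.58^2))
  expect_equal(spi$f_0r[1], 4.4222, tolerance = 1e-3)
  expect_equal(max(abs(spi$f_3)), 0)
  # tensor reassembly equals k0^2 (eps - eps_rm I)
  fv <- uniaxial_field(array(2.52, c(1, 1, 3)), 0.03,
                       array(c(0.3, 1.2, 2.9), c(1, 1, 3)),
                       array(c(0.4, 1.0, 2.2), c(1, 1, 3)))
  sp <- scattering_potential_from_material(fv, g)
  for (i in 1:3) {
    f0 <- sp$f_0r[1, 1, i]
    Mf <- matrix(c(f0 + sp$f_1c[1, 1, i], sp$f_1s[1, 1, i], sp$f_2c[1, 1, i],
                   sp$f_1s[1, 1, i], f0 - sp$f_1c[1, 1, i], sp$f_2s[1, 1, i],
                   sp$f_2c[1, 1, i], sp$f_2s[1, 1, i], f0 + sp$f_3[1, 1, i]),
                 3, 3)
    Me <- g$k0^2 * (permittivity_matrix(fv$eps_mean[1, 1, i],
                                        fv$delta_eps[1, 1, i],
                                        fv$omega[1, 1, i],
                                        fv$theta[1, 1, i]) -
                      g$eps_rm * diag(3))
    expect_equal(Mf, Me, tolerance = 1e-12)
  }
})

test_that("material extraction round-trips on realizable voxels (both signs)", {
  set.seed(21)
  n <- 1000
  g <- pti_grid(c(1, 1, n), c(0.2, 0.1, 0.1), 0.532, 1.515)
  for (s in c(1, -1)) {
    de <- s * runif(n, 1e-4, 0.05)
    fld <- uniaxial_field(array(runif(n, 2.25, 2.34), c(1, 1, n)),
                          array(de, c(1, 1, n)),
                          array(runif(n, 0, pi), c(1, 1, n)),
                          array(runif(n, 0, pi), c(1, 1, n)))
    sp <- scattering_potential_from_material(fld, g)
    rec <- material_from_scattering_potential(sp, s, g)
    # round trip through the five anisotropic components is exact
    sp2 <- scattering_potential_from_material(
      uniaxial_field(rec$eps_mean + g$eps_rm, rec$delta_eps,
                     rec$omega, rec$theta), g)
    for (l in c("f_1c", "f_1s", "f_2c", "f_2s", "f_3", "f_0r"))
      expect_lt(max(abs(sp[[l]] - sp2[[l]])), 1e-9)
    expect_lt(max(abs(rec$delta_eps - fld$delta_eps)), 1e-9)
    expect_lt(max(abs(rec$eps_mean - (fld$eps_mean - g$eps_rm))), 1e-9)
  }
  # known voxel: (contrast 0.04, +0.0384, omega 30 deg, theta 60 deg)
  fld <- uniaxial_field(array(g$eps_rm + 0.04, c(1, 1, 1)), 0.0384,
                        pi / 6, pi / 3)
  sp <- scattering_potential_from_material(fld, g = pti_grid(c(1, 1, 1),
    c(0.2, 0.1, 0.1), 0.532, 1.515))
  rec <- material_from_scattering_potential(sp, +1)
  expect_equal(rec$omega[1], pi / 6, tolerance = 1e-12)
  expect_equal(rec$theta[1], pi / 3, tolerance = 1e-12)
  expect_equal(rec$delta_eps[1], 0.0384, tolerance = 1e-12)
  expect_equal(rec$eps_mean[1], 0.04, tolerance = 1e-12)
})

test_that("degenerate voxels take the documented defaults", {
  g <- pti_grid(c(1, 1, 2), c(0.2, 0.1, 0.1), 0.532, 1.515)
  sp <- scattering_potential_zero <- ptir:::scattering_potential_zero(g)
  rec <- material_from_scattering_potential(sp, +1, g)
  expect_equal(unique(as.vector(rec$delta_eps)), 0)
  expect_equal(unique(as.vector(rec$omega)), 0)
  expect_equal(unique(as.vector(rec$theta)), pi / 2)
})

test_that("sign flip of anisotropic components swaps the branches (omega + 90 deg)", {
  set.seed(31)
  n <- 200
  g <- pti_grid(c(1, 1, n), c(0.2, 0.1, 0.1), 0.532, 1.515)
  fld <- uniaxial_field(array(runif(n, 2.25, 2.34), c(1, 1, n)),
                        array(runif(n, 1e-3, 0.05), c(1, 1, n)),
                        array(runif(n, 0, pi), c(1, 1, n)),
                        array(runif(n, 0.3, pi - 0.3), c(1, 1, n)))
  sp <- scattering_potential_from_material(fld, g)
  spf <- sp
  for (l in c("f_1c", "f_1s", "f_2c", "f_2s", "f_3")) spf[[l]] <- -sp[[l]]
  plus_flip <- material_from_scattering_potential(spf, +1, g)
  minus_orig <- material_from_scattering_potential(sp, -1, g)
  expect_equal(plus_flip$theta, minus_orig$theta, tolerance = 1e-9)
  expect_lt(max(axis_diff(plus_flip$omega, minus_orig$omega)), 1e-9)
  expect_equal(abs(plus_flip$delta_eps), abs(minus_orig$delta_eps),
               tolerance = 1e-9)
  # for an exactly in-plane voxel the apparent axis rotates by 90 degrees
  g1 <- pti_grid(c(1, 1, 1), c(0.2, 0.1, 0.1), 0.532, 1.515)
  v <- uniaxial_field(array(2.35, c(1, 1, 1)), 0.03, pi / 6, pi / 2)
  spv <- scattering_potential_from_material(v, g1)
  for (l in c("f_1c", "f_1s", "f_2c", "f_2s", "f_3")) spv[[l]] <- -spv[[l]]
  w <- material_from_scattering_potential(spv, +1, g1)
  expect_equal(axis_diff(w$omega[1], pi / 6), pi / 2, tolerance = 1e-9)
})

test_that("out_of_plane_tilt folds inclination about the focal plane", {
  expect_equal(out_of_plane_tilt(pi / 2), 0)
  expect_equal(out_of_plane_tilt(0), pi / 2)
  expect_equal(out_of_plane_tilt(pi / 3), pi / 6)
  expect_equal(out_of_plane_tilt(2 * pi / 3), pi / 6)
  expect_error(out_of_plane_tilt(3.5), "theta")
})
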