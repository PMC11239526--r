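# Nonlinear single-scattering (vector Born) simulator and the fast
# linearized forward model.

#' Tilted plane wave with transported circular polarization
#'
#' Unit-amplitude plane wave incident from transverse frequency `nu_perp`
#' (cycles/um), with the circular polarization transported along meridians
#' (s/p decomposition on the sphere). The axial phase uses the grid-snapped
#' axial frequency (see the package discretization notes) so that plane
#' waves are exactly periodic on the grid.
#'
#' @param nu_perp `(nu_y, nu_x)` transverse spatial frequency, inside the
#'   propagating band `|nu_perp| < n_m/lambda0`.
#' @param polarization `"rcp"` or `"lcp"`.
#' @param grid a [pti_grid()].
#' @return `pti_vector_field`: complex volumes `Ex`, `Ey`, `Ez` with
#'   attributes `e` (Jones vector) and `shat` (unit propagation direction).
#' @export
incident_field <- function(nu_perp, polarization = "rcp", grid) {
  stopifnot(inherits(grid, "pti_grid"))
  nubar <- grid$medium_index / grid$wavelength_um
  ur2 <- sum(nu_perp^2)
  if (ur2 >= nubar^2) stop("evanescent source frequency: |nu_perp| >= n_m/lambda0")
  eta <- sqrt(nubar^2 - ur2)
  nzdz <- grid$shape[1] * grid$spacing[1]
  eta_snap <- round(eta * nzdz) / nzdz
  beta <- acos(min(eta / nubar, 1))
  phi <- atan2(nu_perp[1], nu_perp[2])
  e <- polarization_jones(beta, phi, polarization)[, 1]
  co <- grid_coords(grid)
  ramp <- outer(exp(2i * pi * eta_snap * co$z),
                outer(exp(2i * pi * nu_perp[1] * co$y),
                      exp(2i * pi * nu_perp[2] * co$x)))
  out <- list(Ex = e[1] * ramp, Ey = e[2] * ramp, Ez = e[3] * ramp)
  attr(out, "e") <- e
  attr(out, "shat") <- c(nu_perp[2], nu_perp[1], eta) / nubar  # (x, y, z)
  attr(out, "grid") <- grid
  class(out) <- "pti_vector_field"
  out
}

# pointwise product of the scattering potential tensor with a vector field:
# V = f E, using the seven-component decomposition.
sp_apply_field <- function(sp, Ex, Ey, Ez) {
  f0 <- sp$f_0r + 1i * sp$f_0i
  list(
    Vx = (f0 + sp$f_1c) * Ex + sp$f_1s * Ey + sp$f_2c * Ez,
    Vy = sp$f_1s * Ex + (f0 - sp$f_1c) * Ey + sp$f_2s * Ez,
    Vz = sp$f_2c * Ex + sp$f_2s * Ey + (f0 + sp$f_3) * Ez)
}

# pad/crop helpers for open-space convolution
pad_array <- function(a, shape) {
  out <- array(0i, shape)
  d <- dim(a)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

#' Single-scattering (first Born) vector field
#'
#' Computes `E_out = E_inc + G * (f E_inc)` where `G` is the open-space
#' dyadic Green's tensor (angular-spectrum form with forward and backward
#' branches) and `*` is 3D convolution, evaluated by FFT on a zero-padded
#' grid to suppress wrap-around. Linear in the scattering potential.
#'
#' @param sp a `pti_scattering_potential`.
#' @param e_inc a `pti_vector_field` (see [incident_field()]); any incident
#'   field is accepted.
#' @param grid a [pti_grid()].
#' @param pad integer padding voxels per axis `(z, y, x)`; default half the
#'   grid along each axis.
#' @return `pti_vector_field` with the scattered-plus-incident field.
#' @export
born_scatter <- function(sp, e_inc, grid, pad = NULL) {
  stopifnot(inherits(sp, "pti_scattering_potential"),
            inherits(e_inc, "pti_vector_field"))
  if (!identical(dim(sp$f_0r), dim(e_inc$Ex))) stop("shapes disagree")
  s0 <- grid$shape
  if (is.null(pad)) pad <- ceiling(s0 / 2)
  sP <- s0 + 2L * as.integer(pad)
  gP <- pti_grid(sP, grid$spacing, grid$wavelength_um, grid$medium_index)
  gre <- greens_tensor_spectrum(gP)
  ny <- sP[2]; nx <- sP[3]; nz <- sP[1]
  dz <- grid$spacing[1]
  V <- sp_apply_field(sp, e_inc$Ex, e_inc$Ey, e_inc$Ez)
  W <- lapply(V, function(v) fftxy(pad_array(v, sP)))

  zoff <- fft_offsets(nz, dz)
  eta <- gre$eta; amp <- gre$amp
  # forward / backward one-sided kernels along z (z = 0 plane belongs to +)
  expf <- exp(2i * pi * outer(zoff * (zoff >= 0), as.vector(eta)))  # nz x nt
  expb <- exp(-2i * pi * outer(zoff * (zoff < 0), as.vector(eta)))
  ampv <- as.vector(amp) * dz
  Kf <- sweep(expf * (zoff >= 0), 2, ampv, "*")
  Kb <- sweep(expb * (zoff < 0), 2, ampv, "*")
  Kf_hat <- stats::mvfft(Kf)
  Kb_hat <- stats::mvfft(Kb)

  # projectors for forward (+) and backward (-) propagation
  Pp <- matrix(0, ny * nx, 9); Pm <- matrix(0, ny * nx, 9)
  for (p in 1:3) for (q in 1:3) {
    v <- as.vector(gre$projector[, , p, q])
    Pp[, p + 3L * (q - 1L)] <- v
    flip <- xor(p == 3, q == 3)
    Pm[, p + 3L * (q - 1L)] <- if (flip) -v else v
  }

  conv_branch <- function(Wj, Khat) {
    # z-convolution: mvfft along z of each transverse column, multiply, invert
    d <- dim(Wj)
    m <- matrix(Wj, d[1], d[2] * d[3])
    mh <- stats::mvfft(m) * Khat
    array(stats::mvfft(mh, inverse = TRUE) / d[1], d)
  }
  Wf <- lapply(W, conv_branch, Khat = Kf_hat)
  Wb <- lapply(W, conv_branch, Khat = Kb_hat)

  comp_field <- function(p) {
    accf <- matrix(0i, nz, ny * nx)
    accb <- matrix(0i, nz, ny * nx)
    for (j in 1:3) {
      cpj <- p + 3L * (j - 1L)
      accf <- accf + sweep(matrix(Wf[[j]], nz, ny * nx), 2, Pp[, cpj], "*")
      accb <- accb + sweep(matrix(Wb[[j]], nz, ny * nx), 2, Pm[, cpj], "*")
    }
    es <- fftxy(array(accf + accb, sP), inverse = TRUE)
    es[seq_len(s0[1]), seq_len(s0[2]), seq_len(s0[3])]
  }
  out <- list(Ex = e_inc$Ex + comp_field(1),
              Ey = e_inc$Ey + comp_field(2),
              Ez = e_inc$Ez + comp_field(3))
  attr(out, "grid") <- grid
  class(out) <- "pti_vector_field"
  out
}

# ---- partially coherent Stokes simulation --------------------------------

# source-independent spectral detection kernel on a grid:
# amp * Dirichlet(eta_u - u_z) with the objective pupil applied.
detection_kernel <- function(grid, detection) {
  gre <- greens_tensor_spectrum(grid)
  tf <- transverse_freqs(grid)
  nz <- grid$shape[1]; ny <- grid$shape[2]; nx <- grid$shape[3]
  dz <- grid$spacing[1]
  pupil <- sqrt(tf$ur2) * grid$wavelength_um <= detection$na_obj &
    as.vector(gre$mask)
  amp <- rep(0i, ny * nx)
  amp[pupil] <- 1i * dz / (4 * pi * as.vector(gre$eta)[pupil])
  uz <- grid_frequencies(grid)$uz
  D <- dirichlet_sum(outer(as.vector(gre$eta), uz, "-") * (2 * pi * dz), nz)
  dim(D) <- c(ny * nx, nz)
  G3 <- aperm(array(D * amp, c(ny, nx, nz)), c(3, 1, 2))  # (nz, ny, nx)
  P <- matrix(0, ny * nx, 9)
  for (p in 1:3) for (q in 1:3)
    P[, p + 3L * (q - 1L)] <- as.vector(gre$projector[, , p, q])
  Parr <- lapply(1:9, function(k) array(rep(P[, k], each = nz), c(nz, ny, nx)))
  list(G3 = G3, P = Parr, pupil = matrix(pupil, ny, nx))
}

#' Simulate polarization-resolved Stokes volumes (vector Born model)
#'
#' For each illumination pattern, sums incoherently over the pattern's
#' discrete plane-wave sources the coherency products of the detected
#' (objective-pupil-filtered, refocused) scattered-plus-incident field.
#' Returns generalized Stokes volumes `S0..S3`; the quadratic
#' (scattered x scattered) term is retained, so this simulator is nonlinear
#' in the specimen and serves as the reference for the linearized model.
#'
#' @param field a [uniaxial_field()] (absolute `eps_mean`), or a
#'   `pti_scattering_potential`.
#' @param patterns list of `pti_pattern`.
#' @param detection a [detection_spec()].
#' @param grid a [pti_grid()].
#' @param verbose progress messages.
#' @return `pti_stokes`: `stokes[[alpha]]` with volumes `S0, S1, S2, S3`,
#'   plus `grid` and `pattern_labels`. Empty specimens give spatially
#'   constant `S0` (and constant, pattern-dependent `S1`, `S2` backgrounds).
#' @export
simulate_stokes <- function(field, patterns, detection, grid,
                            verbose = FALSE) {
  sp <- if (inherits(field, "pti_scattering_potential")) field
        else scattering_potential_from_material(field, grid)
  ker <- detection_kernel(grid, detection)
  co <- grid_coords(grid)
  nz <- grid$shape[1]
  out <- vector("list", length(patterns))
  for (a in seq_along(patterns)) {
    st <- source_table(patterns[[a]], grid)
    Sxx <- array(0, grid$shape); Syy <- array(0, grid$shape)
    Sxy <- array(0i, grid$shape)
    for (s in seq_len(st$n)) {
      e <- st$e[, s]
      ramp <- outer(exp(2i * pi * st$eta_snap[s] * co$z),
                    outer(exp(2i * pi * st$uy[s] * co$y),
                          exp(2i * pi * st$ux[s] * co$x)))
      V <- sp_apply_field(sp, e[1] * ramp, e[2] * ramp, e[3] * ramp)
      W <- lapply(V, fft3)
      Ehat_x <- ker$G3 * (ker$P[[1]] * W[[1]] + ker$P[[4]] * W[[2]] +
                            ker$P[[7]] * W[[3]])
      Ehat_y <- ker$G3 * (ker$P[[2]] * W[[1]] + ker$P[[5]] * W[[2]] +
                            ker$P[[8]] * W[[3]])
      # incident wave passes if inside the detection pupil
      pass <- ker$pupil[st$iy[s] + 1L, st$ix[s] + 1L]
      Ex <- ifft3(Ehat_x) + (if (pass) e[1] * ramp else 0)
      Ey <- ifft3(Ehat_y) + (if (pass) e[2] * ramp else 0)
      w <- st$weight[s]
      Sxx <- Sxx + w * (Mod(Ex)^2)
      Syy <- Syy + w * (Mod(Ey)^2)
      Sxy <- Sxy + w * Ex * Conj(Ey)
    }
    out[[a]] <- list(S0 = Sxx + Syy, S1 = Sxx - Syy,
                     S2 = 2 * Re(Sxy), S3 = -2 * Im(Sxy))
    if (verbose) message("pattern ", a, " simulated (", st$n, " sources)")
  }
  res <- list(stokes = out, grid = grid,
              pattern_labels = vapply(patterns, function(p) p$label, ""),
              prime = FALSE)
  class(res) <- "pti_stokes"
  res
}

#' @export
print.pti_stokes <- function(x, ...) {
  cat(sprintf("pti_stokes%s: %d patterns on %s grid\n",
              if (isTRUE(x$prime)) " (DC-normalized S')" else "",
              length(x$stokes), paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Constant empty-field Stokes background of an acquisition plan
#'
#' The Stokes background of an empty specimen is spatially constant per
#' pattern: `S_pq = sum_nu w_nu e_p e_q^*`. Oblique sources carry nonzero
#' constant `S1`/`S2` (instrument polarization), removed downstream by
#' [background_correct()].
#'
#' @inheritParams simulate_stokes
#' @return matrix `n_patterns x 4` with columns `S0, S1, S2, S3`.
#' @export
stokes_background <- function(patterns, detection, grid) {
  ker <- detection_kernel(grid, detection)
  t(vapply(patterns, function(p) {
    st <- source_table(p, grid)
    pass <- ker$pupil[cbind(st$iy + 1L, st$ix + 1L)]
    w <- st$weight * pass
    sxx <- sum(w * Mod(st$e[1, ])^2)
    syy <- sum(w * Mod(st$e[2, ])^2)
    sxy <- sum(w * st$e[1, ] * Conj(st$e[2, ]))
    c(S0 = sxx + syy, S1 = sxx - syy, S2 = 2 * Re(sxy), S3 = -2 * Im(sxy))
  }, numeric(4)))
}

#' Linearized forward model: Stokes spectra from transfer functions
#'
#' Applies `S'_m,alpha(u) = sum_l H[m,l,alpha](u) f_l(u)` per frequency and
#' inverse-transforms; exactly linear in the scattering potential and real
#' valued (Hermitian transfer functions). Outputs are DC-normalized S'
#' (background `S0` divided out, constant backgrounds absent).
#'
#' @param sp a `pti_scattering_potential`.
#' @param tfset a `pti_tfset` from [compute_transfer_functions()] (3D) or
#'   [project_otf_2d()] (2D; `sp` must then be one voxel thick and is
#'   interpreted as a z-integrated 2D potential).
#' @return `pti_stokes` with `prime = TRUE` and channels `S0, S1, S2`.
#' @export
simulate_linear_stokes <- function(sp, tfset) {
  stopifnot(inherits(sp, "pti_scattering_potential"),
            inherits(tfset, "pti_tfset"))
  grid <- tfset$grid
  comp <- sp_component_names
  if (tfset$mode == "3D") {
    if (!identical(dim(sp$f_0r), as.integer(grid$shape)))
      stop("scattering potential grid does not match transfer functions")
    fh <- lapply(comp, function(l) fft3(sp[[l]]))
  } else {
    fh <- lapply(comp, function(l) {
      sl <- sp[[l]]
      if (length(dim(sl)) == 3) sl <- apply(sl, c(2, 3), sum) * grid$spacing[1]
      stats::fft(sl)
    })
  }
  names(fh) <- comp
  out <- lapply(tfset$H, function(Ha) {
    S <- lapply(1:3, function(m) {
      acc <- fh[[1]] * Ha[[m]][[1]]
      for (l in 2:7) acc <- acc + fh[[l]] * Ha[[m]][[l]]
      if (tfset$mode == "3D") Re(ifft3(acc))
      else Re(stats::fft(acc, inverse = TRUE)) / length(acc)
    })
    names(S) <- c("S0", "S1", "S2")
    S
  })
  res <- list(stokes = out, grid = grid, pattern_labels = tfset$pattern_labels,
              prime = TRUE)
  class(res) <- "pti_stokes"
  res
}
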