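# Illumination, pupils, dyadic Green's spectrum and the vectorial transfer
# functions of the linearized single-scattering model.
#
# Discretization contract (shared with the nonlinear simulator so that the
# linear parts of the two pipelines agree to machine precision):
#  * source points live on the transverse frequency lattice of the grid;
#  * the axial frequency of each discrete plane wave is snapped to the
#    nearest axial DFT frequency (polarization and projectors use the exact
#    direction); this makes the forward operator DFT-diagonal;
#  * spectra are periodic: shifted pupils wrap (choose dx so that
#    (NA_illu + NA_obj)/lambda0 fits below the transverse Nyquist band).

#' Oblique illumination patterns: brightfield disk plus annular sectors
#'
#' Builds the default acquisition plan of one full circular (brightfield)
#' pattern and `n_sectors` annular sector patterns rotated in equal steps,
#' each a set of non-negative source weights on the transverse frequency
#' lattice of `grid`. The defaults produce the nine-pattern plan used for
#' tensor imaging: 1 disk + 8 sectors of 90 degree width at 45 degree steps,
#' with inner radius `na_inner = 0.3 * na_illu`.
#'
#' @param grid a [pti_grid()]; the pupil lattice is the grid's transverse
#'   frequency lattice.
#' @param na_illu illumination numerical aperture (`<= medium_index`).
#' @param n_sectors number of sector patterns (`>= 3`).
#' @param sector_width_deg angular width of each sector in degrees.
#' @param include_brightfield prepend the full-disk pattern.
#' @param na_inner inner NA of the sector annulus (`< na_illu`).
#' @param rotation_deg rotate all sector centres by this angle.
#' @param source_stride keep every `source_stride`-th lattice point along
#'   each pupil axis (deterministic subsampling that trades angular sampling
#'   density for speed; 1 = every in-band point).
#' @param polarization incident polarization, `"rcp"` (default) or `"lcp"`.
#' @return list of `pti_pattern` objects, each with fields `weights`
#'   (ny x nx matrix, FFT order), `polarization` and `label`.
#' @export
sector_patterns <- function(grid, na_illu, n_sectors = 8,
                            sector_width_deg = 90, include_brightfield = TRUE,
                            na_inner = 0.3 * na_illu, rotation_deg = 0,
                            source_stride = 1L, polarization = "rcp") {
  stopifnot(inherits(grid, "pti_grid"))
  if (n_sectors < 3) stop("n_sectors must be >= 3")
  if (na_inner >= na_illu) stop("na_inner must be < na_illu")
  if (na_illu > grid$medium_index)
    stop("na_illu cannot exceed the medium index")
  tf <- transverse_freqs(grid)
  ny <- grid$shape[2]; nx <- grid$shape[3]
  r <- sqrt(tf$ur2) * grid$wavelength_um        # NA units
  ang <- atan2(tf$uy, tf$ux)
  iy <- rep(seq_len(ny) - 1L, times = nx)
  ix <- rep(seq_len(nx) - 1L, each = ny)
  keep <- (iy %% source_stride == 0L) & (ix %% source_stride == 0L)

  mk <- function(mask, label) {
    w <- matrix(0, ny, nx)
    w[mask & keep] <- 1
    if (sum(w) <= 0) stop("pattern '", label, "' has no source points; ",
                          "increase the grid size or reduce source_stride")
    p <- list(weights = w, polarization = polarization, label = label)
    class(p) <- "pti_pattern"
    p
  }

  pats <- list()
  if (include_brightfield)
    pats[["bf"]] <- mk(r <= na_illu, "bf")
  hw <- sector_width_deg * pi / 360            # half width, radians
  centers <- rotation_deg * pi / 180 + 2 * pi * (seq_len(n_sectors) - 1) / n_sectors
  annulus <- r <= na_illu & r > na_inner
  for (k in seq_len(n_sectors)) {
    dphi <- ((ang - centers[k]) + pi) %% (2 * pi) - pi
    lab <- sprintf("sector%02d", k)
    pats[[lab]] <- mk(annulus & abs(dphi) <= hw, lab)
  }
  pats
}

#' Detection specification
#'
#' @param na_obj detection numerical aperture (`0 < na_obj <= medium index`).
#' @param analyzer_angles four distinct linear analyzer orientations in
#'   degrees (defaults 0, 45, 90, 135).
#' @return `pti_detection` object.
#' @export
detection_spec <- function(na_obj, analyzer_angles = c(0, 45, 90, 135)) {
  if (na_obj <= 0) stop("na_obj must be positive")
  if (length(analyzer_angles) != 4 || anyDuplicated(analyzer_angles %% 180))
    stop("need four distinct analyzer angles")
  structure(list(na_obj = na_obj, analyzer_angles = analyzer_angles),
            class = "pti_detection")
}

# s/p-transported circular polarization for propagation direction
# (beta, phi): RCP = exp(-i phi) (p_hat - i s_hat)/sqrt(2) which reduces to
# (x - i y)/sqrt(2) on axis (S3 = -1 with the exp(-i w t) convention).
polarization_jones <- function(beta, phi, polarization = "rcp") {
  sh <- rbind(-sin(phi), cos(phi), rep(0, length(phi)))
  ph <- rbind(cos(beta) * cos(phi), cos(beta) * sin(phi), -sin(beta))
  if (identical(polarization, "rcp")) {
    e <- sweep(ph - 1i * sh, 2, exp(-1i * phi), "*") / sqrt(2)
  } else if (identical(polarization, "lcp")) {
    e <- sweep(ph + 1i * sh, 2, exp(1i * phi), "*") / sqrt(2)
  } else stop("polarization must be 'rcp' or 'lcp'")
  e  # 3 x n complex
}

#' Dyadic Green's tensor spectrum (angular-spectrum form)
#'
#' For every transverse frequency `u_perp` inside the propagating band
#' (`|u_perp| <= na_cutoff/lambda0`), the far-field dyadic Green's tensor
#' reduces to the transverse projector `I - s s^T` (with `s` the unit
#' forward propagation direction on the Ewald sphere) times the scalar
#' angular-spectrum propagator `i exp(2i pi eta z) / (4 pi eta)`,
#' `eta = sqrt((n_m/lambda0)^2 - |u_perp|^2)`. Evanescent frequencies are
#' zeroed.
#'
#' @param grid a [pti_grid()].
#' @param na_cutoff cutoff NA (defaults to the medium index: full
#'   propagating band).
#' @return `pti_greens` object: `eta` (ny x nx, cycles/um, 0 where
#'   evanescent), `mask` (logical ny x nx), `projector` (ny x nx x 3 x 3),
#'   `amp = i/(4 pi eta)` masked (complex ny x nx), `shat` (ny x nx x 3).
#' @export
greens_tensor_spectrum <- function(grid, na_cutoff = grid$medium_index) {
  stopifnot(inherits(grid, "pti_grid"))
  tf <- transverse_freqs(grid)
  ny <- grid$shape[2]; nx <- grid$shape[3]
  nubar <- grid$medium_index / grid$wavelength_um
  cut <- na_cutoff / grid$wavelength_um
  mask <- tf$ur2 <= cut^2 & tf$ur2 < nubar^2
  eta <- sqrt(pmax(nubar^2 - tf$ur2, 0))
  eta[!mask] <- 0
  sx <- tf$ux / nubar; sy <- tf$uy / nubar; sz <- eta / nubar
  sx[!mask] <- 0; sy[!mask] <- 0; sz[!mask] <- 0
  proj <- array(0, c(ny, nx, 3, 3))
  s <- list(sx, sy, sz)
  for (p in 1:3) for (q in 1:3) {
    proj[, , p, q] <- matrix((p == q) * mask - s[[p]] * s[[q]] * mask, ny, nx)
  }
  amp <- matrix(0i, ny, nx)
  amp[mask] <- 1i / (4 * pi * eta[mask])
  out <- list(eta = matrix(eta, ny, nx), mask = matrix(mask, ny, nx),
              projector = proj, amp = amp,
              shat = array(c(sx, sy, sz), c(ny, nx, 3)), grid = grid,
              na_cutoff = na_cutoff)
  class(out) <- "pti_greens"
  out
}

# ---- internal geometry shared by simulator and transfer functions --------

# Per-pattern table of discrete sources: 0-based lattice indices, physical
# transverse frequencies, exact and grid-snapped axial frequencies, unit
# direction, transported polarization and weight.
source_table <- function(pattern, grid) {
  w <- pattern$weights
  ny <- grid$shape[2]; nx <- grid$shape[3]
  fr <- grid_frequencies(grid)
  sel <- which(w > 0)
  iy <- (sel - 1L) %% ny
  ix <- (sel - 1L) %/% ny
  uy <- fr$uy[iy + 1L]; ux <- fr$ux[ix + 1L]
  nubar <- grid$medium_index / grid$wavelength_um
  ur2 <- uy^2 + ux^2
  ok <- ur2 < nubar^2
  iy <- iy[ok]; ix <- ix[ok]; uy <- uy[ok]; ux <- ux[ok]
  weight <- w[sel][ok]
  eta <- sqrt(nubar^2 - (uy^2 + ux^2))
  nzdz <- grid$shape[1] * grid$spacing[1]
  eta_snap <- round(eta * nzdz) / nzdz
  beta <- acos(pmin(eta / nubar, 1))
  phi <- atan2(uy, ux)
  e <- polarization_jones(beta, phi, pattern$polarization)
  list(iy = iy, ix = ix, uy = uy, ux = ux, eta = eta, eta_snap = eta_snap,
       weight = weight, e = e, n = length(weight))
}

# Dirichlet kernel: sum_{j=-floor(n/2)}^{ceil(n/2)-1} exp(i phi j)
dirichlet_sum <- function(phi, n) {
  z <- exp(1i * phi)
  num <- 1 - exp(1i * phi * n)
  den <- 1 - z
  out <- exp(-1i * phi * floor(n / 2)) * num / den
  deg <- abs(den) < 1e-9
  out[deg] <- n
  out
}

# circular-shift lookup indices: t(iy,ix) -> (iy + sy, ix + sx) mod n
shift_index <- function(sy, sx, ny, nx) {
  py <- ((seq_len(ny) - 1L + sy) %% ny) + 1L
  px <- ((seq_len(nx) - 1L + sx) %% nx) + 1L
  as.vector(outer(py, (px - 1L) * ny, "+"))
}
# reflected shift: t(iy,ix) -> (sy - iy, sx - ix) mod n
reflect_index <- function(sy, sx, ny, nx) {
  py <- ((sy - (seq_len(ny) - 1L)) %% ny) + 1L
  px <- ((sx - (seq_len(nx) - 1L)) %% nx) + 1L
  as.vector(outer(py, (px - 1L) * ny, "+"))
}

# component basis: f = (f_0r + i f_0i) I + f_1c B1c + ... ; returns B_l e
component_vectors <- function(e) {
  list(f_0r = e,
       f_0i = e,                                    # imaginary unit handled by kappa
       f_1c = c(e[1], -e[2], 0),
       f_1s = c(e[2], e[1], 0),
       f_2c = c(e[3], 0, e[1]),
       f_2s = c(0, e[3], e[2]),
       f_3  = c(0, 0, e[3]))
}
component_kappa <- c(f_0r = 1 + 0i, f_0i = 0 + 1i, f_1c = 1 + 0i,
                     f_1s = 1 + 0i, f_2c = 1 + 0i, f_2s = 1 + 0i,
                     f_3 = 1 + 0i)

#' Vectorial transfer functions of the linearized forward model
#'
#' Assembles the complex transfer functions `H[m, l, alpha](u)` that map the
#' 3D spectra of the seven scattering-potential components `f_l` to the
#' DC-normalized Stokes spectra `S'_m` (`m = 0, 1, 2`) recorded under each
#' illumination pattern `alpha`. Each pattern's functions are the weighted
#' sum over its discrete sources of the cross-correlation between the
#' source-polarized incident wave and the Green's-tensor-filtered detection
#' pupil response, normalized by the pattern's transverse background
#' intensity so that the model background `S0 = 1`.
#'
#' Linear analyzers measure only `S0..S2`, so no `m = 3` channel is built.
#'
#' @param patterns list of `pti_pattern` (see [sector_patterns()]).
#' @param detection a [detection_spec()].
#' @param grid a [pti_grid()].
#' @param verbose print progress per pattern.
#' @return `pti_tfset`: `H[[alpha]][[m]][[l]]` complex `(nz, ny, nx)` arrays
#'   in FFT order, plus `grid`, `detection`, `pattern_labels`, `background`
#'   (per-pattern transverse DC intensity before normalization).
#' @export
compute_transfer_functions <- function(patterns, detection, grid,
                                       verbose = FALSE) {
  stopifnot(inherits(grid, "pti_grid"), inherits(detection, "pti_detection"))
  nz <- grid$shape[1]; ny <- grid$shape[2]; nx <- grid$shape[3]
  nt <- ny * nx
  dz <- grid$spacing[1]
  gre <- greens_tensor_spectrum(grid)
  tf <- transverse_freqs(grid)
  pupil <- as.numeric(sqrt(tf$ur2) * grid$wavelength_um <= detection$na_obj &
                        as.vector(gre$mask))
  eta_u <- as.vector(gre$eta)
  # i dz /(4 pi eta) * pupil, 0 outside the band
  amp <- rep(0i, nt)
  ok <- pupil > 0
  amp[ok] <- 1i * dz / (4 * pi * eta_u[ok])
  P <- matrix(0, nt, 9)   # projector entries, column p + 3(q-1)
  for (p in 1:3) for (q in 1:3)
    P[, p + 3L * (q - 1L)] <- as.vector(gre$projector[, , p, q])
  uz <- grid_frequencies(grid)$uz
  comp <- sp_component_names

  H <- vector("list", length(patterns))
  background <- numeric(length(patterns))
  for (a in seq_along(patterns)) {
    st <- source_table(patterns[[a]], grid)
    if (st$n < 1) stop("pattern ", a, " has no propagating sources")
    acc <- lapply(1:3, function(m)
      lapply(comp, function(l) matrix(0i, nt, nz)))
    B <- 0; S1bg <- 0; S2bg <- 0
    for (s in seq_len(st$n)) {
      e <- st$e[, s]
      wgt <- st$weight[s]
      B <- B + wgt * (Mod(e[1])^2 + Mod(e[2])^2)
      S1bg <- S1bg + wgt * (Mod(e[1])^2 - Mod(e[2])^2)
      S2bg <- S2bg + wgt * 2 * Re(e[1] * Conj(e[2]))
      i2 <- shift_index(st$iy[s], st$ix[s], ny, nx)
      i1 <- reflect_index(st$iy[s], st$ix[s], ny, nx)
      a2 <- amp[i2]; a1 <- Conj(amp[i1])
      # Dirichlet kernels in u_z
      K2 <- dirichlet_sum(outer(eta_u[i2] - st$eta_snap[s], uz, "-") *
                            (2 * pi * dz), nz)
      K1 <- dirichlet_sum(outer(st$eta_snap[s] - eta_u[i1], uz, "-") *
                            (2 * pi * dz), nz)
      dim(K2) <- c(nt, nz); dim(K1) <- c(nt, nz)
      cv <- component_vectors(e)
      for (l in seq_along(comp)) {
        cl <- cv[[comp[l]]]
        kap <- component_kappa[[comp[l]]]
        # detected transverse components of the projected source vector
        p2x <- (P[i2, 1] * cl[1] + P[i2, 4] * cl[2] + P[i2, 7] * cl[3])
        p2y <- (P[i2, 2] * cl[1] + P[i2, 5] * cl[2] + P[i2, 8] * cl[3])
        p1x <- Conj(P[i1, 1] * cl[1] + P[i1, 4] * cl[2] + P[i1, 7] * cl[3])
        p1y <- Conj(P[i1, 2] * cl[1] + P[i1, 5] * cl[2] + P[i1, 8] * cl[3])
        A2x <- kap * a2 * p2x; A2y <- kap * a2 * p2y
        A1x <- Conj(kap) * a1 * p1x; A1y <- Conj(kap) * a1 * p1y
        ex <- e[1]; ey <- e[2]
        t2_0 <- (Conj(ex) * A2x + Conj(ey) * A2y)
        t1_0 <- (ex * A1x + ey * A1y)
        t2_1 <- (Conj(ex) * A2x - Conj(ey) * A2y)
        t1_1 <- (ex * A1x - ey * A1y)
        t2_2 <- (Conj(ey) * A2x + Conj(ex) * A2y)
        t1_2 <- (ex * A1y + ey * A1x)
        acc[[1]][[l]] <- acc[[1]][[l]] + wgt * (t2_0 * K2 + t1_0 * K1)
        acc[[2]][[l]] <- acc[[2]][[l]] + wgt * (t2_1 * K2 + t1_1 * K1)
        acc[[3]][[l]] <- acc[[3]][[l]] + wgt * (t2_2 * K2 + t1_2 * K1)
      }
    }
    # normalize by the pattern's background (model S0 background = 1) and
    # fold in the linear effect of the ratio-form background correction:
    # corrected S1 = S1/S0 - S1bg/S0bg has linear model H1 - (S1bg/B) H0
    # (same for S2), since division by S0 mixes the S0 signal into S1/S2
    # wherever the empty-field polarization background is nonzero.
    Ha <- lapply(1:3, function(m) {
      out <- lapply(seq_along(comp), function(l) {
        M <- acc[[m]][[l]] / B
        if (m == 2) M <- M - (S1bg / B) * acc[[1]][[l]] / B
        if (m == 3) M <- M - (S2bg / B) * acc[[1]][[l]] / B
        aperm(array(M, c(ny, nx, nz)), c(3, 1, 2))
      })
      names(out) <- comp
      out
    })
    H[[a]] <- Ha
    background[a] <- B
    if (verbose) message("pattern ", a, "/", length(patterns), " done (",
                         st$n, " sources)")
  }
  out <- list(H = H, grid = grid, detection = detection,
              pattern_labels = vapply(patterns, function(p) p$label, ""),
              background = background, mode = "3D")
  class(out) <- "pti_tfset"
  out
}

#' @export
print.pti_tfset <- function(x, ...) {
  cat(sprintf("pti_tfset (%s): %d patterns x 3 Stokes channels x 7 components on %s grid\n",
              x$mode, length(x$H),
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Project a 3D transfer-function set to the thin-specimen 2D model
#'
#' Each 2D transfer function is the axial integral (discrete sum times
#' `du_z`) of the corresponding 3D function: the in-focus response of the
#' system to a specimen confined within the depth of field.
#'
#' @param tfset a 3D `pti_tfset`.
#' @return `pti_tfset` with `mode = "2D"`; `H[[alpha]][[m]][[l]]` are
#'   `(ny, nx)` complex matrices.
#' @export
project_otf_2d <- function(tfset) {
  stopifnot(inherits(tfset, "pti_tfset"))
  if (tfset$mode != "3D") stop("tfset is already 2D")
  duz <- 1 / (tfset$grid$shape[1] * tfset$grid$spacing[1])
  H2 <- lapply(tfset$H, function(Ha)
    lapply(Ha, function(Hm)
      lapply(Hm, function(h) apply(h, c(2, 3), sum) * duz)))
  out <- tfset
  out$H <- H2
  out$mode <- "2D"
  out
}
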