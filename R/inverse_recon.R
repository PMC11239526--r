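# Three-stage inverse algorithm: per-frequency multi-channel Tikhonov
# deconvolution of the seven scattering-potential components, dual-sign
# algebraic property extraction, and optic-sign probability estimation.

#' Reconstruction configuration
#'
#' @param reg_iso Tikhonov weight for the isotropic components
#'   (`f_0r`, `f_0i`), relative to the peak of the normal-matrix diagonal
#'   (dimensionless, `> 0`).
#' @param reg_aniso Tikhonov weight for the five anisotropic components.
#'   Anisotropy is transferred more weakly than phase, so its default is
#'   stiffer.
#' @param optic_sign_window Gaussian smoothing radius (um) for the
#'   optic-sign residual maps.
#' @param anis_floor differential-permittivity magnitude below which the
#'   optic sign is deemed undecidable (`p_plus = 0.5`).
#' @param mode `"3D"` or `"2D"` (thin specimen, projected transfer
#'   functions).
#' @return `pti_recon_config`.
#' @export
recon_config <- function(reg_iso = 1e-3, reg_aniso = 5e-3,
                         optic_sign_window = 0.5, anis_floor = 1e-5,
                         mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (reg_iso <= 0 || reg_aniso <= 0) stop("regularization weights must be > 0")
  if (optic_sign_window < 0) stop("optic_sign_window must be >= 0")
  structure(list(reg_iso = reg_iso, reg_aniso = reg_aniso,
                 optic_sign_window = optic_sign_window,
                 anis_floor = anis_floor, mode = mode),
            class = "pti_recon_config")
}

# batched Hermitian positive-definite solve of (M + Lambda) x = b across all
# frequencies: M is a list-of-lists of length-N complex vectors (7x7),
# b a list of 7 vectors. Gaussian elimination without pivoting (Hermitian
# positive definite by construction).
batch_solve7 <- function(M, b, floor_eps = 1e-300) {
  n <- length(b)
  for (k in seq_len(n)) {
    piv <- Re(M[[k]][[k]])
    bad <- piv < floor_eps
    if (any(bad)) {
      warning("singular normal matrix at ", sum(bad),
              " frequencies; regularization floor applied")
      piv[bad] <- floor_eps
    }
    M[[k]][[k]] <- piv
    for (i in seq_len(n)[-seq_len(k)]) {
      fac <- M[[i]][[k]] / piv
      for (j in k:n) M[[i]][[j]] <- M[[i]][[j]] - fac * M[[k]][[j]]
      b[[i]] <- b[[i]] - fac * b[[k]]
    }
  }
  x <- vector("list", n)
  for (k in rev(seq_len(n))) {
    acc <- b[[k]]
    if (k < n) for (j in (k + 1):n) acc <- acc - M[[k]][[j]] * x[[j]]
    x[[k]] <- acc / M[[k]][[k]]
  }
  x
}

#' Multi-channel Tikhonov deconvolution of the scattering potential
#'
#' Per-frequency closed-form solution
#' `f_hat = (H^H H + Lambda)^{-1} H^H S'` stacking all Stokes channels and
#' illumination patterns. `Lambda` is diagonal with `reg_iso` for the two
#' isotropic components and `reg_aniso` for the five anisotropic ones, both
#' scaled by the peak diagonal of `H^H H` so the weights are dimensionless.
#' The zero-frequency bin (not measured by the DC-subtracted data) is forced
#' to zero. Outputs are real volumes; the solver is exactly linear in `S'`.
#'
#' @param s_prime DC-normalized `pti_stokes` (see [normalize_dc()]).
#' @param tfset matching `pti_tfset` (3D or 2D).
#' @param cfg a [recon_config()].
#' @return `pti_scattering_potential` estimate.
#' @export
solve_components <- function(s_prime, tfset, cfg = recon_config()) {
  stopifnot(inherits(s_prime, "pti_stokes"), inherits(tfset, "pti_tfset"))
  if (!isTRUE(s_prime$prime))
    stop("solve_components expects DC-normalized S' data (run normalize_dc)")
  if (length(s_prime$stokes) < 2) stop("need >= 2 patterns for conditioning")
  if (length(s_prime$stokes) != length(tfset$H))
    stop("pattern counts of data and transfer functions disagree")
  grid <- tfset$grid
  comp <- sp_component_names
  is3d <- tfset$mode == "3D"
  tfm <- function(a) if (is3d) fft3(a) else stats::fft(a)
  itfm <- function(a) if (is3d) Re(ifft3(a)) else Re(stats::fft(a, inverse = TRUE)) / length(a)

  M <- lapply(1:7, function(i) lapply(1:7, function(j) 0i))
  bb <- lapply(1:7, function(i) 0i)
  for (a in seq_along(tfset$H)) {
    S <- s_prime$stokes[[a]]
    for (m in 1:3) {
      d <- S[[m]]
      if (is3d && length(dim(d)) != 3) stop("3D transfer functions need 3D data")
      sh <- tfm(d)
      sh[1] <- 0  # DC bin unmeasured
      Hm <- tfset$H[[a]][[m]]
      for (i in 1:7) {
        ci <- Conj(Hm[[i]])
        bb[[i]] <- bb[[i]] + ci * sh
        for (j in i:7) M[[i]][[j]] <- M[[i]][[j]] + ci * Hm[[j]]
      }
    }
  }
  for (i in 2:7) for (j in 1:(i - 1)) M[[i]][[j]] <- Conj(M[[j]][[i]])
  scale <- max(vapply(1:7, function(i) max(Re(M[[i]][[i]])), 0))
  lam <- c(cfg$reg_iso, cfg$reg_iso, rep(cfg$reg_aniso, 5)) * scale
  for (i in 1:7) M[[i]][[i]] <- M[[i]][[i]] + lam[i]

  dims <- if (is3d) grid$shape else grid$shape[2:3]
  Mv <- lapply(M, function(r) lapply(r, function(x) as.vector(x)))
  bv <- lapply(bb, as.vector)
  x <- batch_solve7(Mv, bv)
  sp <- lapply(1:7, function(i) itfm(array(x[[i]], dims)))
  names(sp) <- comp
  sp$grid <- grid
  class(sp) <- "pti_scattering_potential"
  sp
}

#' Dual-sign extraction of physical properties
#'
#' Applies [material_from_scattering_potential()] under the positive and the
#' negative uniaxial assumption, returning both candidate property sets.
#'
#' @param sp estimated `pti_scattering_potential`.
#' @param grid grid of the components (defaults to `sp$grid`).
#' @return list with elements `plus` and `minus`, each a
#'   `pti_uniaxial_field` whose `eps_mean` is the permittivity CONTRAST.
#' @export
extract_properties <- function(sp, grid = sp$grid) {
  list(plus = material_from_scattering_potential(sp, +1, grid),
       minus = material_from_scattering_potential(sp, -1, grid))
}

# recompose scattering-potential components from extracted properties
# (eps_mean field holds the contrast eps_r - eps_rm)
recompose_sp <- function(field, grid) {
  k2 <- grid$k0^2
  de <- field$delta_eps; th <- field$theta; om <- field$omega
  st2 <- sin(th)^2
  sp <- list(
    f_0r = k2 * (field$eps_mean - de * cos(th)^2),
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

#' Optic-sign probability from dual-branch refits
#'
#' Re-synthesizes the DC-normalized Stokes data from the components
#' recomposed under each optic-sign assumption, forms locally windowed
#' residual energies `r_plus`, `r_minus` (Gaussian window of radius
#' `cfg$optic_sign_window`), and reports
#' `p_plus = r_minus / (r_plus + r_minus)`. Voxels with negligible
#' anisotropy (below `cfg$anis_floor`) or vanishing residual contrast get
#' the undecidable value 0.5. Swapping the branches maps `p -> 1 - p`.
#'
#' @param sp solved `pti_scattering_potential`.
#' @param s_prime the DC-normalized data used for the fit.
#' @param tfset matching transfer functions.
#' @param cfg a [recon_config()].
#' @param props optional precomputed [extract_properties()] output.
#' @return list with `p_plus` (array in `[0, 1]`) and the branch fields.
#' @export
estimate_optic_sign <- function(sp, s_prime, tfset, cfg = recon_config(),
                                props = NULL) {
  grid <- tfset$grid
  if (is.null(props)) props <- extract_properties(sp, grid)
  is3d <- tfset$mode == "3D"
  resid_energy <- function(field) {
    synth <- simulate_linear_stokes(recompose_sp(field, grid), tfset)
    r <- 0
    for (a in seq_along(s_prime$stokes))
      for (m in 1:3)
        r <- r + (s_prime$stokes[[a]][[m]] - synth$stokes[[a]][[m]])^2
    r
  }
  rp <- resid_energy(props$plus)
  rm_ <- resid_energy(props$minus)
  if (cfg$optic_sign_window > 0) {
    if (is3d) {
      rp <- gaussian_filter3(rp, cfg$optic_sign_window, grid)
      rm_ <- gaussian_filter3(rm_, cfg$optic_sign_window, grid)
    } else {
      g2 <- pti_grid(c(1, grid$shape[2:3]), grid$spacing, grid$wavelength_um,
                     grid$medium_index)
      dim(rp) <- c(1, dim(rp)); dim(rm_) <- c(1, dim(rm_))
      rp <- gaussian_filter3(rp, c(0, rep(cfg$optic_sign_window, 2)), g2)[1, , ]
      rm_ <- gaussian_filter3(rm_, c(0, rep(cfg$optic_sign_window, 2)), g2)[1, , ]
    }
  }
  tot <- rp + rm_
  p <- array(0.5, dim(tot))
  ok <- tot > .Machine$double.eps
  p[ok] <- rm_[ok] / tot[ok]
  anis <- pmax(abs(props$plus$delta_eps), abs(props$minus$delta_eps))
  p[anis < cfg$anis_floor] <- 0.5
  p <- pmin(pmax(p, 0), 1)
  list(p_plus = p, plus = props$plus, minus = props$minus)
}

#' End-to-end reconstruction of the uniaxial permittivity tensor
#'
#' Composes the full decoding pipeline: raw intensities -> Stokes
#' ([intensities_to_stokes()]) -> [background_correct()] ->
#' [normalize_dc()] -> [solve_components()] -> [extract_properties()] ->
#' [estimate_optic_sign()], then selects each voxel's properties from the
#' higher-probability optic-sign branch (ties go to the positive branch).
#'
#' @param data a `pti_raw` (4 analyzer channels), a `pti_stokes`, or an
#'   already DC-normalized `pti_stokes` (`prime = TRUE`).
#' @param background empty-field `pti_stokes`, a constant background matrix
#'   from [stokes_background()], or `NULL` to skip the correction.
#' @param tfset transfer functions matching the acquisition.
#' @param cfg a [recon_config()].
#' @param instrument instrument matrix used when `data` is raw intensities.
#' @return `pti_result` with per-voxel maps `mean_permittivity`
#'   (`eps_r - eps_rm` contrast), `diff_permittivity` (`|delta_eps|`),
#'   `omega`, `theta`, `p_plus`, plus the solved components in `$components`.
#' @export
reconstruct <- function(data, background = NULL, tfset, cfg = recon_config(),
                        instrument = instrument_matrix()) {
  s <- data
  if (inherits(s, "pti_raw")) s <- intensities_to_stokes(s, instrument)
  if (!isTRUE(s$prime)) {
    if (!is.null(background)) s <- background_correct(s, background)
    s <- normalize_dc(s)
  }
  sp <- solve_components(s, tfset, cfg)
  props <- extract_properties(sp)
  os <- estimate_optic_sign(sp, s, tfset, cfg, props)
  sel <- os$p_plus >= 0.5
  pick <- function(a, b) { a[!sel] <- b[!sel]; a }
  out <- list(
    mean_permittivity = pick(props$plus$eps_mean, props$minus$eps_mean),
    diff_permittivity = abs(pick(props$plus$delta_eps, props$minus$delta_eps)),
    omega = pick(props$plus$omega, props$minus$omega),
    theta = pick(props$plus$theta, props$minus$theta),
    p_plus = os$p_plus,
    components = sp, config = cfg, grid = tfset$grid)
  class(out) <- "pti_result"
  out
}

#' @export
print.pti_result <- function(x, ...) {
  cat(sprintf("pti_result: %s voxels | mean permittivity in [%.4g, %.4g] | max diff permittivity %.4g | mean p+ %.3f\n",
              paste(dim(x$mean_permittivity), collapse = " x "),
              min(x$mean_permittivity), max(x$mean_permittivity),
              max(x$diff_permittivity), mean(x$p_plus)))
  invisible(x)
}
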