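#' Sampling grid for volumes and their frequency spectra
#'
#' A `pti_grid` fixes the voxel lattice, the free-space wavelength and the
#' refractive index of the immersion medium. All volumes in ptir are arrays
#' with dimensions `(nz, ny, nx)`; physical coordinates are in micrometres
#' with the origin at the volume centre. Fourier-domain quantities live on
#' the matching unshifted (FFT-order) frequency lattice in cycles per
#' micrometre; the forward transform convention is `exp(-2i*pi*u.r)`.
#'
#' @param shape integer vector `(nz, ny, nx)`, voxel counts per axis.
#' @param spacing numeric vector `(dz, dy, dx)` in micrometres, all `> 0`.
#' @param wavelength_um free-space wavelength `lambda0` in micrometres.
#' @param medium_index refractive index `n_m >= 1` of the surrounding medium.
#'
#' @return An object of class `pti_grid` with fields `shape`, `spacing`,
#'   `wavelength_um`, `medium_index` and read-only derived quantities
#'   `k0 = 2*pi/lambda0` (rad/um) and `eps_rm = n_m^2`.
#' @examples
#' g <- pti_grid(c(32, 64, 64), c(0.25, 0.1, 0.1), 0.532, 1.515)
#' g$k0
#' @export
pti_grid <- function(shape, spacing, wavelength_um, medium_index) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive voxel counts (nz, ny, nx)")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes (dz, dy, dx) in um")
  if (!is.numeric(wavelength_um) || wavelength_um <= 0)
    stop("wavelength_um must be > 0")
  if (!is.numeric(medium_index) || medium_index < 1)
    stop("medium_index must be >= 1")
  g <- list(shape = shape, spacing = spacing,
            wavelength_um = wavelength_um, medium_index = medium_index,
            k0 = 2 * pi / wavelength_um,
            eps_rm = medium_index^2)
  class(g) <- "pti_grid"
  g
}

#' @export
print.pti_grid <- function(x, ...) {
  cat(sprintf("pti_grid: %d x %d x %d voxels (z,y,x), spacing %.4g/%.4g/%.4g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  lambda0 = %.4g um, n_m = %.4g (k0 = %.4g rad/um, eps_rm = %.5g)\n",
              x$wavelength_um, x$medium_index, x$k0, x$eps_rm))
  invisible(x)
}

# FFT-order frequency samples for n points with spacing d (cycles/um):
# (0, 1, ..., n/2-1, -n/2, ..., -1) / (n*d)
fft_freq <- function(n, d) {
  neg <- if (n >= 2) seq.int(-floor(n / 2), -1L) else integer(0)
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), neg)
  k / (n * d)
}

# FFT-order signed sample offsets (same layout as fft_freq, units of um)
fft_offsets <- function(n, d) {
  neg <- if (n >= 2) seq.int(-floor(n / 2), -1L) else integer(0)
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), neg)
  k * d
}

#' Frequency coordinates of a grid
#'
#' @param grid a [pti_grid()].
#' @return list with `uz`, `uy`, `ux` (FFT-order 1D frequency vectors,
#'   cycles/um) and `du` the frequency steps `(duz, duy, dux)`.
#' @export
grid_frequencies <- function(grid) {
  s <- grid$shape; d <- grid$spacing
  list(uz = fft_freq(s[1], d[1]), uy = fft_freq(s[2], d[2]),
       ux = fft_freq(s[3], d[3]),
       du = 1 / (s * d))
}

# Transverse frequency maps, flattened column-major over (y, x):
# returns uy, ux vectors of length ny*nx and |u_perp|^2.
transverse_freqs <- function(grid) {
  fr <- grid_frequencies(grid)
  uy <- rep(fr$uy, times = grid$shape[3])
  ux <- rep(fr$ux, each = grid$shape[2])
  list(uy = uy, ux = ux, ur2 = uy^2 + ux^2)
}

# Real-space coordinate vectors in natural array order, origin at the
# centre voxel floor(n/2)+1 (constant phase offsets relative to the DFT
# origin cancel in all coherency products).
grid_coords <- function(grid) {
  s <- grid$shape; d <- grid$spacing
  cc <- function(n, dd) (seq_len(n) - 1 - floor(n / 2)) * dd
  list(z = cc(s[1], d[1]), y = cc(s[2], d[2]), x = cc(s[3], d[3]))
}

# ---- FFT helpers ---------------------------------------------------------
# R's fft() is unnormalized; ifft3 divides by the number of elements.

fft3 <- function(a) stats::fft(a)

ifft3 <- function(a) stats::fft(a, inverse = TRUE) / length(a)

# FFT along z only (dimension 1) of a (nz, ny, nx) array.
fftz <- function(a, inverse = FALSE) {
  d <- dim(a)
  m <- stats::mvfft(matrix(a, d[1], d[2] * d[3]), inverse = inverse)
  if (inverse) m <- m / d[1]
  array(m, d)
}

# Transverse (y, x) FFT of each z-slice of a (nz, ny, nx) array.
fftxy <- function(a, inverse = FALSE) {
  d <- dim(a)
  out <- array(0i, d)
  for (iz in seq_len(d[1])) {
    sl <- stats::fft(a[iz, , ], inverse = inverse)
    if (inverse) sl <- sl / (d[2] * d[3])
    out[iz, , ] <- sl
  }
  out
}

# Gaussian low-pass filter (FFT-based, periodic), sigma in um per axis.
gaussian_filter3 <- function(a, sigma_um, grid) {
  fr <- grid_frequencies(grid)
  if (length(sigma_um) == 1) sigma_um <- rep(sigma_um, 3)
  gz <- exp(-2 * pi^2 * sigma_um[1]^2 * fr$uz^2)
  gy <- exp(-2 * pi^2 * sigma_um[2]^2 * fr$uy^2)
  gx <- exp(-2 * pi^2 * sigma_um[3]^2 * fr$ux^2)
  ker <- outer(gz, outer(gy, gx))
  Re(ifft3(fft3(a) * ker))
}

# Box mean filter over a cubic window of half-width hw voxels (periodic).
box_filter3 <- function(a, hw) {
  d <- dim(a)
  kz <- c(rep(1, hw + 1), rep(0, max(d[1] - 2 * hw - 1, 0)), rep(1, min(hw, d[1] - hw - 1)))
  ky <- c(rep(1, hw + 1), rep(0, max(d[2] - 2 * hw - 1, 0)), rep(1, min(hw, d[2] - hw - 1)))
  kx <- c(rep(1, hw + 1), rep(0, max(d[3] - 2 * hw - 1, 0)), rep(1, min(hw, d[3] - hw - 1)))
  ker <- outer(kz, outer(ky, kx))
  ker <- ker / sum(ker)
  Re(ifft3(fft3(a) * Conj(fft3(ker))))
}
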