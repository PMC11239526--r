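# Polarization-camera instrument model: intensities <-> Stokes parameters,
# background correction and DC normalization.

#' Ideal instrument matrix of a four-channel linear-analyzer camera
#'
#' Malus-law rows `0.5 * [1, cos(2 phi_c), sin(2 phi_c)]` mapping
#' `(S0, S1, S2)` to the four analyzer-channel intensities.
#'
#' @param analyzer_angles four analyzer orientations in degrees
#'   (default 0, 45, 90, 135).
#' @return `pti_instrument`: 4x3 matrix `A` with the angles as an attribute.
#' @examples
#' A <- instrument_matrix()
#' A$A %*% c(1, 1, 0) # -> 1, 0.5, 0, 0.5
#' @export
instrument_matrix <- function(analyzer_angles = c(0, 45, 90, 135)) {
  if (length(analyzer_angles) != 4) stop("need four analyzer angles")
  phi <- analyzer_angles * pi / 180
  A <- 0.5 * cbind(1, cos(2 * phi), sin(2 * phi))
  if (qr(A)$rank < 3)
    stop("analyzer angles give a rank-deficient instrument matrix")
  structure(list(A = A, analyzer_angles = analyzer_angles),
            class = "pti_instrument")
}

#' Simulate raw analyzer intensities from Stokes volumes
#'
#' The forward instrument model: `I_c = sum_m A[c, m] S_m` per voxel, for
#' each pattern. Inverse of [intensities_to_stokes()].
#'
#' @param stokes a `pti_stokes` (uses channels `S0, S1, S2`).
#' @param instrument a [instrument_matrix()].
#' @param gain optional scalar exposure factor.
#' @return `pti_raw`: `I[[alpha]][[c]]` intensity volumes plus metadata.
#' @export
stokes_to_intensities <- function(stokes, instrument = instrument_matrix(),
                                  gain = 1) {
  stopifnot(inherits(stokes, "pti_stokes"))
  A <- instrument$A
  I <- lapply(stokes$stokes, function(S) {
    lapply(1:4, function(cch)
      gain * (A[cch, 1] * S$S0 + A[cch, 2] * S$S1 + A[cch, 3] * S$S2))
  })
  out <- list(I = I, grid = stokes$grid, pattern_labels = stokes$pattern_labels,
              instrument = instrument)
  class(out) <- "pti_raw"
  out
}

#' @export
print.pti_raw <- function(x, ...) {
  cat(sprintf("pti_raw: %d patterns x %d analyzer channels on %s grid\n",
              length(x$I), length(x$I[[1]]),
              paste(x$grid$shape, collapse = " x ")))
  invisible(x)
}

#' Convert analyzer intensities to Stokes parameters
#'
#' Per-voxel least-squares solve of the 4-channel instrument model,
#' `S = (A^T A)^{-1} A^T I`; exact when the intensities are consistent.
#'
#' @param raw a `pti_raw` (4 analyzer channels per pattern).
#' @param instrument a [instrument_matrix()] (or a calibrated 4x3 matrix
#'   wrapped in one). An ill-conditioned matrix is rejected with its
#'   condition number.
#' @return `pti_stokes` with channels `S0, S1, S2`.
#' @export
intensities_to_stokes <- function(raw, instrument = instrument_matrix()) {
  stopifnot(inherits(raw, "pti_raw"))
  A <- instrument$A
  if (length(raw$I[[1]]) != 4) stop("expected four analyzer channels")
  kap <- kappa(crossprod(A), exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stop(sprintf("instrument matrix is near-singular (condition number %.3g)", kap))
  pinv <- solve(crossprod(A), t(A))  # 3 x 4
  st <- lapply(raw$I, function(Ia) {
    S <- lapply(1:3, function(m)
      pinv[m, 1] * Ia[[1]] + pinv[m, 2] * Ia[[2]] +
        pinv[m, 3] * Ia[[3]] + pinv[m, 4] * Ia[[4]])
    names(S) <- c("S0", "S1", "S2")
    S
  })
  out <- list(stokes = st, grid = raw$grid, pattern_labels = raw$pattern_labels,
              prime = FALSE)
  class(out) <- "pti_stokes"
  out
}

#' Background correction against an empty-field acquisition
#'
#' Removes instrument polarization using normalized subtraction:
#' `S0_corr = S0 / S0_bg`, `S1_corr = S1/S0 - S1_bg/S0_bg` (same for `S2`).
#' Exact for multiplicative instrument effects and invariant to a common
#' exposure gain. The background may be a single plane per pattern
#' (broadcast along z) or a full matching volume.
#'
#' @param s_sample `pti_stokes` of the specimen acquisition.
#' @param s_bg `pti_stokes` of the empty field, or the `n_patterns x >= 3`
#'   constant matrix from [stokes_background()].
#' @return background-corrected `pti_stokes`.
#' @export
background_correct <- function(s_sample, s_bg) {
  stopifnot(inherits(s_sample, "pti_stokes"))
  get_bg <- function(a) {
    if (is.matrix(s_bg)) {
      list(S0 = s_bg[a, 1], S1 = s_bg[a, 2], S2 = s_bg[a, 3])
    } else {
      b <- s_bg$stokes[[a]]
      bz <- function(v) if (length(v) == 1 || is.null(dim(v))) v
        else if (identical(dim(v), dim(s_sample$stokes[[a]]$S0))) v
        else array(rep(as.vector(v[1, , ]), each = dim(s_sample$stokes[[a]]$S0)[1]),
                   dim(s_sample$stokes[[a]]$S0))
      list(S0 = bz(b$S0), S1 = bz(b$S1), S2 = bz(b$S2))
    }
  }
  st <- lapply(seq_along(s_sample$stokes), function(a) {
    S <- s_sample$stokes[[a]]
    B <- get_bg(a)
    if (any(B$S0 == 0)) stop("background S0 contains zeros")
    list(S0 = S$S0 / B$S0,
         S1 = S$S1 / S$S0 - B$S1 / B$S0,
         S2 = S$S2 / S$S0 - B$S2 / B$S0)
  })
  out <- s_sample
  out$stokes <- st
  out$background_corrected <- TRUE
  out
}

#' DC normalization producing the model's S' channels
#'
#' Per pattern: `S0' = (S0 - mean(S0)) / mean(S0)`, `S1' = S1 / mean(S0)`,
#' `S2' = S2 / mean(S0)`, with the mean taken over the volume. This is the
#' DC-subtracted, exposure-invariant input of the linearized inverse model.
#'
#' @param s a `pti_stokes` (typically after [background_correct()]).
#' @return `pti_stokes` with `prime = TRUE`.
#' @export
normalize_dc <- function(s) {
  stopifnot(inherits(s, "pti_stokes"))
  st <- lapply(s$stokes, function(S) {
    m <- mean(S$S0)
    if (!is.finite(m) || m <= 0) stop("mean S0 must be positive")
    list(S0 = (S$S0 - m) / m, S1 = S$S1 / m, S2 = S$S2 / m)
  })
  out <- s
  out$stokes <- st
  out$prime <- TRUE
  out
}
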