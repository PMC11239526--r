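# Shared optical setups, built on first use and cached for the session.
# Grids are scaled down from the instrument's native sampling so the full
# pipeline stays within the test-suite time budget; tolerances are never
# adjusted to the smaller grids.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  fx <- switch(name,
    # small setup for optics/forward consistency tests
    "small" = {
      grid <- pti_grid(c(24, 24, 24), c(0.15, 0.1, 0.1), 0.532, 1.515)
      detection <- detection_spec(1.2)
      patterns <- sector_patterns(grid, na_illu = 1.0, source_stride = 3)
      tfs <- compute_transfer_functions(patterns, detection, grid)
      bg <- stokes_background(patterns, detection, grid)
      list(grid = grid, detection = detection, patterns = patterns,
           tfs = tfs, bg = bg)
    },
    # instrument-like setup (NA 1.4 / 1.47, oil immersion) for recovery tests
    "std" = {
      grid <- pti_grid(c(32, 32, 32), c(0.14, 0.09, 0.09), 0.532, 1.515)
      detection <- detection_spec(1.47)
      patterns <- sector_patterns(grid, na_illu = 1.4, source_stride = 2)
      tfs <- compute_transfer_functions(patterns, detection, grid)
      bg <- stokes_background(patterns, detection, grid)
      list(grid = grid, detection = detection, patterns = patterns,
           tfs = tfs, bg = bg)
    },
    stop("unknown fixture ", name))
  .fixture_cache[[name]] <- fx
  fx
}

# circular difference of two axis angles (period pi), radians
axis_diff <- function(a, b) abs(((a - b + pi / 2) %% pi) - pi / 2)

# relative L2 mismatch between two DC-normalized Stokes sets (means removed
# channel-wise, since the nonlinear data loses its exact DC to the
# normalization statistics)
stokes_rel_mismatch <- function(s_test, s_ref) {
  num <- 0; den <- 0
  for (a in seq_along(s_ref$stokes)) for (m in 1:3) {
    r <- s_ref$stokes[[a]][[m]]; r <- r - mean(r)
    t <- s_test$stokes[[a]][[m]]; t <- t - mean(t)
    num <- num + sum((t - r)^2); den <- den + sum(r^2)
  }
  sqrt(num / den)
}
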