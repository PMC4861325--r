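# Shared fixtures and independent oracles. The default phantom pipeline is
# expensive (~10 s), so it is built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Default 4-region phantom at the stated noise levels, acquired at
# 160 um/s with a 0.625 s scan period (2 scans per 200 um pixel) and
# binned on a ~5.2e4-channel axis.
phantom_fixture <- function() {
  if (is.null(.fixtures$noisy)) {
    ph <- make_phantom(default_phantom_spec(seed = 7), 200)
    sim <- simulate_acquisition(
      ph, acq = list(velocity_x_um_s = 160, scan_period_s = 0.625), seed = 7)
    axis <- build_mz_axis(400, 1000, 850, 0.015, 0.03)
    cube <- build_cube(sim$stream, sim$track, axis, pitch_x_um = 200)
    .fixtures$noisy <- list(ph = ph, sim = sim, axis = axis, cube = cube,
                            V = pixel_matrix(cube))
  }
  .fixtures$noisy
}

# Same phantom with all noise sources off (gain, jitter, background).
noise_free_fixture <- function() {
  if (is.null(.fixtures$clean)) {
    ph <- make_phantom(default_phantom_spec(
      seed = 7, pixel_gain_sigma = 0, mz_jitter_sigma_at_ref = 0,
      background_peak_rate = 0), 200)
    sim <- simulate_acquisition(
      ph, acq = list(velocity_x_um_s = 160, scan_period_s = 0.625), seed = 7)
    axis <- build_mz_axis(400, 1000, 850, 0.015, 0.03)
    cube <- build_cube(sim$stream, sim$track, axis, pitch_x_um = 200)
    .fixtures$clean <- list(ph = ph, sim = sim, axis = axis, cube = cube,
                            V = pixel_matrix(cube))
  }
  .fixtures$clean
}

# An axis with exactly `n` channels (for small random-cube oracle tests).
make_axis_n <- function(n, ref_bin_width = 0.85) {
  r <- ref_bin_width / 850
  build_mz_axis(400, 400 * (1 + r)^(n - 0.5), 850, ref_bin_width, 2 * ref_bin_width)
}

# Random small non-negative sparse cube for dense-oracle tests.
rand_cube <- function(rows, cols, n_channels, seed, density = 0.3) {
  axis <- make_axis_n(n_channels)
  V <- with_seed(seed, abs(Matrix::rsparsematrix(rows * cols, axis$n, density)))
  structure(list(rows = as.integer(rows), cols = as.integer(cols), axis = axis,
                 pitch_x_um = 1, pitch_y_um = 1, x0_um = 0, y0_um = 0,
                 V = V),
            class = "msi_cube")
}

# with_seed is internal; re-derive it here so tests do not reach into the
# namespace for anything but exported API plus this RNG hygiene helper.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# --- independent oracles ----------------------------------------------------

# Dense Gaussian-window binning over the full axis (no candidate-window
# shortcuts): the brute-force counterpart of bin_scan.
dense_bin_oracle <- function(mz, intensity, axis) {
  out <- numeric(axis$n)
  for (p in seq_along(mz)) {
    if (mz[p] < axis$mz_lo || mz[p] > axis$mz_hi) next
    sig <- (axis$ref_sigma / axis$ref_mz) * mz[p]
    w <- exp(-(axis$centers - mz[p])^2 / (2 * sig^2))
    w[abs(axis$centers - mz[p]) > 4 * sig] <- 0
    out <- out + intensity[p] * w / sum(w)
  }
  out
}

# Direct-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Neutral formulas (as count vectors) for oracle mass computations.
ATOMIC <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
            P = 30.97376163, S = 31.97207100, Cl = 34.96885268)
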