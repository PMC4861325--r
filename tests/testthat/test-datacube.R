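# A minimal hand-built track: two lines, constant velocity 100 um/s,
# 10 s per line, line step 50 um.
toy_track <- function() {
  structure(list(
    samples = data.frame(time_s = c(0, 10, 12, 22),
                         x_um = c(0, 1000, 0, 1000),
                         y_um = c(25, 25, 75, 75)),
    velocity_x_um_s = 100, line_step_um = 50,
    pass_windows = data.frame(line_index = 1:2, t_start = c(0, 12),
                              t_end = c(10, 22))),
    class = "stage_track")
}

test_that("constant-velocity scans are assigned equally spaced x positions", {
  tr <- toy_track()
  times <- c(seq(0, 9.9, by = 1), seq(12, 21.9, by = 1))
  ap <- assign_pixels(tr, times, pitch_x_um = 100)
  for (df in split(ap$assignment, ap$assignment$line_index)) {
    expect_equal(diff(df$x_um), rep(100, nrow(df) - 1), tolerance = 1e-12)
  }
  expect_equal(ap$grid_x, seq(0, 900, by = 100))
})

test_that("scans outside pass windows are discarded; sparse lines are rejected", {
  tr <- toy_track()
  times <- c(seq(0, 9, by = 1), 10.5, 11.5, seq(12, 21, by = 1))  # flyback scans
  ap <- assign_pixels(tr, times, pitch_x_um = 100)
  expect_identical(nrow(ap$assignment), 20L)
  expect_error(assign_pixels(tr, c(seq(0, 9, 1), 13), 100), "line 2 has 1 scan")
})

test_that("grid points coinciding with scan x reproduce that scan's spectrum; random grids match a brute-force interpolation oracle", {
  ax <- make_axis_n(400)
  tr <- toy_track()
  times <- with_seed(4, sort(c(runif(15, 0, 10), runif(15, 12, 22))))
  scans <- with_seed(5, lapply(times, function(t) {
    n <- sample(3:8, 1)
    list(time_s = t, mz = sort(runif(n, ax$mz_lo + 1, ax$mz_hi - 1)),
         intensity = runif(n, 1, 10))
  }))
  stream <- structure(list(scans = scans, times = times), class = "scan_stream")
  cube <- build_cube(stream, tr, ax, pitch_x_um = 37)
  ap <- assign_pixels(tr, times, pitch_x_um = 37)
  # dense per-channel linear interpolation oracle for line 1
  l1 <- ap$assignment[ap$assignment$line_index == 1, ]
  dense <- vapply(which(ap$assignment$line_index == 1), function(i) {
    v <- bin_scan(scans[[ap$assignment$scan[i]]], ax)
    as.numeric(v)
  }, numeric(ax$n))
  for (g in seq(1, length(ap$grid_x), by = 3)) {
    xg <- ap$grid_x[g]
    got <- as.numeric(cube$V[g, ])  # row-major: line 1 pixels come first
    if (xg < min(l1$x_um) - 1e-9 || xg > max(l1$x_um) + 1e-9) {
      expect_equal(sum(got), 0)
      next
    }
    expected <- apply(dense, 1, function(ch) approx(l1$x_um, ch, xout = xg)$y)
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # identity: a grid point exactly on a scan's x reproduces its binned
  # vector (single-line track, so the grid origin is that line's first scan)
  tr1 <- structure(list(
    samples = tr$samples[1:2, ], velocity_x_um_s = 100, line_step_um = 50,
    pass_windows = tr$pass_windows[1, ]), class = "stage_track")
  st1 <- structure(list(scans = scans[seq_len(nrow(l1))],
                        times = times[seq_len(nrow(l1))]),
                   class = "scan_stream")
  cube2 <- build_cube(st1, tr1, ax, pitch_x_um = l1$x_um[2] - l1$x_um[1])
  expect_equal(as.numeric(cube2$V[2, ]),
               as.numeric(bin_scan(scans[[l1$scan[2]]], ax)),
               tolerance = 1e-12)
})

test_that("assembly shapes, padding and conservation", {
  ax <- make_axis_n(50)
  mk <- function(ncol) with_seed(ncol, abs(Matrix::rsparsematrix(ax$n, ncol, 0.3)))
  lines <- list(mk(3), mk(3))
  cube <- assemble_cube(lines, ax, 10, 10)
  expect_identical(c(cube$rows, cube$cols), c(2L, 3L))
  expect_equal(sum(cube$V), sum(lines[[1]]) + sum(lines[[2]]))
  expect_message(assemble_cube(list(mk(3), mk(2)), ax, 10, 10), "padding")
})

test_that("dense-equivalent storage reproduces 904 binary GB for the published shape", {
  expect_identical(dense_storage_gb(805, 59, 2556741), 904)
})

test_that("TIC matches single-element cubes and the dense oracle", {
  cube <- rand_cube(1, 4, 30, seed = 1, density = 0)
  cube$V[3, 17] <- 5
  tic <- tic_image(cube)
  expect_equal(tic[1, 3], 5)
  expect_equal(sum(tic), 5)
  cube <- rand_cube(5, 5, 100, seed = 2)
  expect_equal(as.vector(t(tic_image(cube))),
               apply(as.matrix(cube$V), 1, sum), tolerance = 1e-12)
})

test_that("extracted ion images: whole-axis window equals TIC; dense oracle", {
  cube <- rand_cube(4, 6, 120, seed = 3)
  full <- extracted_ion_image(cube, mean(range(cube$axis$centers)),
                              diff(range(cube$axis$centers)))
  expect_equal(full, tic_image(cube), tolerance = 1e-12)
  target <- cube$axis$centers[60]
  tol <- 10 * mz_bin_width_at(cube$axis, target)
  img <- extracted_ion_image(cube, target, tol)
  sel <- abs(cube$axis$centers - target) <= tol
  dense <- as.matrix(cube$V)[, sel, drop = FALSE]
  expect_equal(as.vector(t(img)), rowSums(dense), tolerance = 1e-12)
  between <- (cube$axis$centers[60] + cube$axis$centers[61]) / 2
  expect_error(extracted_ion_image(cube, between, 1e-9 * between), "nearest")
})

test_that("ROI mean spectra: identity, linearity and ellipse oracle", {
  cube <- rand_cube(6, 6, 80, seed = 4)
  m <- matrix(FALSE, 6, 6); m[2, 3] <- TRUE
  expect_equal(roi_mean_spectrum(cube, roi_selection(mask = m)),
               as.numeric(cube$V[(2 - 1) * 6 + 3, ]), tolerance = 1e-12)
  all_roi <- roi_selection(mask = matrix(TRUE, 6, 6))
  expect_equal(sum(roi_mean_spectrum(cube, all_roi)), mean(tic_image(cube)),
               tolerance = 1e-12)
  roi <- roi_selection(center = c(3, 4), semi_axes = c(2, 1.5))
  got <- roi_mean_spectrum(cube, roi)
  inside <- matrix(FALSE, 6, 6)
  for (r in 1:6) for (c in 1:6) {
    inside[r, c] <- ((r - 3) / 2)^2 + ((c - 4) / 1.5)^2 <= 1
  }
  px <- which(as.vector(t(inside)))
  expect_equal(got, colMeans(as.matrix(cube$V)[px, , drop = FALSE]),
               tolerance = 1e-12)
  expect_error(roi_mean_spectrum(cube, roi_selection(mask = matrix(FALSE, 6, 6))),
               "no pixels")
})

test_that("sparsity accounting matches a dense recount", {
  cube <- rand_cube(4, 5, 60, seed = 5, density = 0.2)
  dense <- as.matrix(cube$V)
  expect_equal(nnz_fraction(cube), mean(dense != 0))
})

test_that("phantom cube: TIC positive on tissue, zero off-tissue; base peaks land within one bin", {
  fx <- noise_free_fixture()
  tic <- tic_image(fx$cube)
  expect_true(all(tic[fx$ph$label_image > 0] > 0))
  expect_true(all(tic[fx$ph$label_image == 0] == 0))
  # round-trip: argmax channel of every tissue pixel is its region base peak
  base_mz <- vapply(fx$ph$region_profile, function(p) {
    pr <- fx$ph$profiles[[p]]
    pr$mz[pr$rel_intensity == 1]
  }, numeric(1))
  tV <- methods::as(Matrix::t(fx$V), "CsparseMatrix")
  amax_idx <- vapply(seq_len(ncol(tV)), function(j) {
    rng <- seq.int(tV@p[j] + 1L, length.out = tV@p[j + 1L] - tV@p[j])
    if (length(rng) == 0L) return(NA_integer_)
    (tV@i[rng] + 1L)[which.max(tV@x[rng])]
  }, integer(1))
  amax <- fx$axis$centers[amax_idx]
  lab <- as.vector(t(fx$ph$label_image))
  for (l in seq_along(base_mz)) {
    sel <- lab == l
    expect_true(all(abs(amax[sel] - base_mz[l]) <=
                      mz_bin_width_at(fx$axis, base_mz[l])))
  }
})

test_that("intensity is conserved from in-range peaks through binning and assembly", {
  fx <- noise_free_fixture()
  total_peaks <- sum(vapply(fx$sim$stream$scans,
                            function(s) sum(s$intensity), numeric(1)))
  binned <- vapply(fx$sim$stream$scans,
                   function(s) sum(bin_scan(s, fx$axis)), numeric(1))
  expect_equal(sum(binned), total_peaks, tolerance = 1e-9)
  # phantom contrast mirror: PI(38:4) image higher on non-tumor tissue than cyst
  img <- extracted_ion_image(fx$cube, 885.5499, 0.01)
  non_tumor <- fx$ph$label_image %in% which(fx$ph$labels %in% c("ovary", "uterus"))
  cyst <- fx$ph$label_image == which(fx$ph$labels == "cyst")
  expect_gt(mean(img[non_tumor]), mean(img[cyst]))
})
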