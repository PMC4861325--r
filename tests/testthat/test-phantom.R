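two_ellipse_spec <- function(seed = 1L, ...) {
  prof <- list(a = data.frame(mz = 500, rel_intensity = 1, n_chlorine = 0L),
               b = data.frame(mz = 600, rel_intensity = 1, n_chlorine = 0L))
  phantom_spec(
    width_um = 2000, height_um = 2000,
    regions = list(
      list(label = "left", shape = "ellipse", params = c(500, 600, 300, 400),
           profile = "a"),
      list(label = "right", shape = "ellipse", params = c(1500, 1300, 350, 250),
           profile = "b")),
    profiles = prof, seed = seed, ...)
}

test_that("a full-frame region labels every pixel", {
  spec <- phantom_spec(
    width_um = 1000, height_um = 800,
    regions = list(list(label = "all", shape = "rect",
                        params = c(0, 0, 1000, 800), profile = "p")),
    profiles = list(p = data.frame(mz = 500, rel_intensity = 1,
                                   n_chlorine = 0L)))
  ph <- make_phantom(spec, 100)
  expect_true(all(ph$label_image == 1L))
  expect_identical(dim(ph$label_image), c(8L, 10L))
})

test_that("ellipse masks match a brute-force rasterization of the inequality", {
  ph <- make_phantom(two_ellipse_spec(), 100)  # 20 x 20 grid
  expect_identical(dim(ph$label_image), c(20L, 20L))
  # brute force: test every pixel center against each ellipse inequality
  counts <- c(0L, 0L)
  expected <- matrix(0L, 20, 20)
  for (row in 1:20) for (col in 1:20) {
    cx <- (col - 0.5) * 100; cy <- (row - 0.5) * 100
    if (((cx - 500) / 300)^2 + ((cy - 600) / 400)^2 <= 1) expected[row, col] <- 1L
    if (((cx - 1500) / 350)^2 + ((cy - 1300) / 250)^2 <= 1) expected[row, col] <- 2L
  }
  expect_identical(ph$label_image, expected)
  expect_identical(as.integer(table(factor(ph$label_image, levels = 0:2))),
                   as.integer(table(factor(expected, levels = 0:2))))
})

test_that("phantom generation is deterministic and overlaps are rejected", {
  expect_identical(make_phantom(two_ellipse_spec(), 100)$label_image,
                   make_phantom(two_ellipse_spec(), 100)$label_image)
  bad <- phantom_spec(
    width_um = 1000, height_um = 1000,
    regions = list(
      list(label = "one", shape = "rect", params = c(0, 0, 600, 600),
           profile = "a"),
      list(label = "two", shape = "rect", params = c(400, 400, 900, 900),
           profile = "b")),
    profiles = list(a = data.frame(mz = 500, rel_intensity = 1, n_chlorine = 0L),
                    b = data.frame(mz = 600, rel_intensity = 1, n_chlorine = 0L)))
  expect_error(make_phantom(bad, 100), "one.*two|two.*one")
})

test_that("spec invariants are enforced at construction", {
  p1 <- data.frame(mz = 500, rel_intensity = 0.5, n_chlorine = 0L)
  expect_error(phantom_spec(1000, 1000,
    regions = list(list(label = "r", shape = "rect", params = c(0, 0, 100, 100),
                        profile = "p")),
    profiles = list(p = p1)), "base peak")
  expect_error(phantom_spec(1000, 1000,
    regions = list(list(label = "r", shape = "ellipse",
                        params = c(100, 100, 300, 50), profile = "p")),
    profiles = list(p = data.frame(mz = 1, rel_intensity = 1, n_chlorine = 0L))),
    "outside")
})

test_that("first-pass scan count per line equals floor(traverse_time / period)", {
  ph <- make_phantom(two_ellipse_spec(), 100)
  for (period in c(0.625, 1.7)) {
    sim <- simulate_acquisition(ph, acq = list(velocity_x_um_s = 160,
                                               scan_period_s = period))
    t_line <- 2000 / 160
    pw <- sim$track$pass_windows
    for (l in seq_len(nrow(pw))) {
      n_l <- sum(sim$stream$times >= pw$t_start[l] &
                   sim$stream$times <= pw$t_end[l])
      expect_identical(n_l, as.integer(floor(t_line / period)))
    }
    # time consistency: every scan time falls inside some pass window
    inside <- vapply(sim$stream$times, function(t)
      any(t >= pw$t_start & t <= pw$t_end), logical(1))
    expect_true(all(inside))
  }
  expect_error(
    simulate_acquisition(ph, acq = list(velocity_x_um_s = 160,
                                        scan_period_s = 1000)),
    "zero scans")
})

test_that("noise-free acquisition emits exactly the profile m/z values", {
  spec <- phantom_spec(
    width_um = 800, height_um = 400,
    regions = list(list(label = "t", shape = "rect", params = c(0, 0, 800, 400),
                        profile = "p")),
    profiles = list(p = data.frame(mz = c(500.25, 600.5, 700.75),
                                   rel_intensity = c(1, 0.5, 0.25),
                                   n_chlorine = c(0L, 1L, 0L))),
    pixel_gain_sigma = 0, mz_jitter_sigma_at_ref = 0,
    background_peak_rate = 0)
  ph <- make_phantom(spec, 100)
  sim <- simulate_acquisition(ph, acq = list(velocity_x_um_s = 160,
                                             scan_period_s = 0.625))
  allowed <- c(500.25, 600.5, 600.5 + 1.99705, 700.75)
  for (sc in sim$stream$scans) {
    expect_identical(sc$mz, sort(allowed))
    expect_true(all(diff(sc$mz) > 0))
    expect_true(all(sc$intensity >= 0))
    # M+2 partner of the n_chlorine = 1 peak at the isotopic ratio
    expect_equal(sc$intensity[sc$mz == 600.5 + 1.99705] /
                   sc$intensity[sc$mz == 600.5], 0.3196)
  }
})

test_that("mean observed M+2/M ratio over 500 noisy scans is near 0.3196", {
  fx <- phantom_fixture()
  ph <- fx$ph
  # tumor pixels hold the 572.4815 chloride adduct
  tumor_scans <- Filter(function(sc) {
    any(abs(sc$mz - 572.4815) < 0.05)
  }, fx$sim$stream$scans)
  expect_gte(length(tumor_scans), 500)
  ratios <- vapply(head(tumor_scans, 500), function(sc) {
    m <- sum(sc$intensity[abs(sc$mz - 572.4815) < 0.05])
    m2 <- sum(sc$intensity[abs(sc$mz - 574.47855) < 0.05])
    m2 / m
  }, numeric(1))
  expect_gte(mean(ratios), 0.30)
  expect_lte(mean(ratios), 0.34)
})

test_that("acquisition is deterministic and geometrically consistent", {
  ph <- make_phantom(two_ellipse_spec(), 100)
  a <- simulate_acquisition(ph, acq = list(velocity_x_um_s = 160,
                                           scan_period_s = 0.625), seed = 3)
  b <- simulate_acquisition(ph, acq = list(velocity_x_um_s = 160,
                                           scan_period_s = 0.625), seed = 3)
  expect_identical(a, b)
  # jitter-free pixel-position recovery: interpolated x equals v * j * period
  ap <- assign_pixels(a$track, a$stream$times, pitch_x_um = 100)
  per_line <- split(ap$assignment, ap$assignment$line_index)
  for (df in per_line) {
    expect_equal(df$x_um, 160 * 0.625 * (seq_len(nrow(df)) - 1),
                 tolerance = 1e-12)
  }
})
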