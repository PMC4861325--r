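# Synthetic tissue phantoms and comb-raster DESI acquisition simulation.
#
# The phantom is a stated world used by every downstream test: spatially
# contiguous regions (ovary, uterus, tumor, blood-filled cyst on an
# off-tissue background) with distinct centroid spectral profiles, a
# multiplicative per-pixel lognormal gain, additive Poisson-count background
# peaks uniform in m/z, Gaussian m/z jitter proportional to m/z, and the
# 35Cl/37Cl M+2 isotope doublet for chloride adducts.

# 37Cl - 35Cl mass difference (Th) and isotope abundance ratio 24.22/75.77,
# the physical constants behind the "3:1" chloride M+2 argument.
CL_M2_SPACING <- 1.99705
CL_M2_RATIO <- 0.3196

#' Define a tissue phantom
#'
#' @param width_um,height_um Phantom extent in micrometers.
#' @param regions List of regions, each a list with `label` (character),
#'   `shape` (`"ellipse"` or `"rect"`), `params` (ellipse: `c(cx, cy, rx, ry)`;
#'   rect: `c(x0, y0, x1, y1)`, all in micrometers) and `profile` (a name in
#'   `profiles`).
#' @param profiles Named list of spectral profiles; each profile is a
#'   data.frame with columns `mz` (Th), `rel_intensity` (fraction of the
#'   region base peak, in (0, 1], with exactly one peak at 1) and
#'   `n_chlorine` (count of chlorine atoms; peaks with `n_chlorine >= 1`
#'   are emitted together with an M+2 isotope partner).
#' @param pixel_gain_sigma Lognormal sigma of the per-pixel multiplicative
#'   gain (dimensionless; 0 disables gain noise).
#' @param mz_jitter_sigma_at_ref Gaussian m/z jitter sigma at m/z 850, in Th;
#'   scaled as `sigma(m) = (mz_jitter_sigma_at_ref / 850) * m`.
#' @param background_peak_rate Expected number of background peaks per scan
#'   (Poisson count, uniform random m/z over the acquisition range).
#' @param base_intensity Intensity of a region base peak before gain, in
#'   arbitrary counts.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_um, height_um, regions, profiles,
                         pixel_gain_sigma = 0.25,
                         mz_jitter_sigma_at_ref = 0.003,
                         background_peak_rate = 3,
                         base_intensity = 1000,
                         seed = 1L) {
  check_scalar_pos(width_um, "width_um")
  check_scalar_pos(height_um, "height_um")
  stopifnot(is.list(regions), length(regions) >= 1L, is.list(profiles))
  if (pixel_gain_sigma < 0 || mz_jitter_sigma_at_ref < 0 ||
      background_peak_rate < 0) {
    stop_("noise parameters must be >= 0")
  }
  labs <- vapply(regions, function(r) r$label, character(1))
  if (anyDuplicated(labs)) stop_("duplicated region labels: %s",
                                 paste(labs[duplicated(labs)], collapse = ", "))
  for (rg in regions) {
    if (!rg$shape %in% c("ellipse", "rect")) {
      stop_("region '%s': unknown shape '%s'", rg$label, rg$shape)
    }
    if (is.null(profiles[[rg$profile]])) {
      stop_("region '%s' references unknown profile '%s'", rg$label, rg$profile)
    }
    p <- rg$params
    bounds_ok <- if (rg$shape == "ellipse") {
      p[1] - p[3] >= 0 && p[1] + p[3] <= width_um &&
        p[2] - p[4] >= 0 && p[2] + p[4] <= height_um
    } else {
      p[1] >= 0 && p[3] <= width_um && p[2] >= 0 && p[4] <= height_um &&
        p[1] < p[3] && p[2] < p[4]
    }
    if (!bounds_ok) stop_("region '%s' mask lies outside [0,%g]x[0,%g]",
                          rg$label, width_um, height_um)
  }
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    stopifnot(all(c("mz", "rel_intensity", "n_chlorine") %in% names(pr)))
    if (any(pr$rel_intensity <= 0 | pr$rel_intensity > 1)) {
      stop_("profile '%s': rel_intensity must lie in (0, 1]", nm)
    }
    if (sum(pr$rel_intensity == 1) != 1L) {
      stop_("profile '%s' must have exactly one base peak (rel_intensity == 1)", nm)
    }
    if (any(pr$n_chlorine < 0)) stop_("profile '%s': n_chlorine must be >= 0", nm)
  }
  structure(
    list(width_um = width_um, height_um = height_um, regions = regions,
         profiles = profiles, pixel_gain_sigma = pixel_gain_sigma,
         mz_jitter_sigma_at_ref = mz_jitter_sigma_at_ref,
         background_peak_rate = background_peak_rate,
         base_intensity = base_intensity, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' The default four-region reproductive-tract phantom
#'
#' Mimics a whole-reproductive-system section: a healthy ovary and uterus
#' dominated by PI(38:4) at m/z 885.5499, a tumor region enriched in the
#' ceramide/sphingomyelin chloride adducts and other annotated tumor species,
#' and a blood-filled cyst dominated by bilirubin, all on an off-tissue
#' background (label 0).
#'
#' @param seed Integer seed stored in the spec.
#' @param pixel_gain_sigma,mz_jitter_sigma_at_ref,background_peak_rate Noise
#'   parameters, see [phantom_spec()].
#' @return A `phantom_spec` for an 8000 x 12000 um frame (40 x 60 pixels at
#'   the default 200 um pitch).
#' @export
default_phantom_spec <- function(seed = 1L,
                                 pixel_gain_sigma = 0.25,
                                 mz_jitter_sigma_at_ref = 0.003,
                                 background_peak_rate = 3) {
  prof <- function(mz, ri, ncl = 0L) {
    data.frame(mz = mz, rel_intensity = ri,
               n_chlorine = rep_len(ncl, length(mz)))
  }
  profiles <- list(
    # healthy ovary: PI(38:4) base plus cholesterol sulfate (ovary-enriched)
    ovary = prof(c(885.5499, 465.3044, 857.5111, 833.5120),
                 c(1.00, 0.25, 0.06, 0.05)),
    # uterus: PI(38:4) base with the PE/PS/PG complement
    uterus = prof(c(885.5499, 716.5247, 722.5070, 746.5053, 766.5324,
                    788.5369, 747.5108, 810.5229),
                  c(1.00, 0.45, 0.25, 0.30, 0.25, 0.35, 0.20, 0.15)),
    # tumor: Table-1-style species; chloride adducts flagged n_chlorine = 1
    tumor = prof(
      c(572.4815, 682.5911, 684.6067, 536.5048, 646.6144, 648.6300,
        599.3202, 583.2562, 524.2994, 480.3096, 465.3044, 436.2834,
        464.3147, 626.5285, 656.5754, 658.5910, 737.5370, 847.6465,
        885.5499),
      c(1.00, 0.55, 0.50, 0.30, 0.25, 0.22,
        0.20, 0.15, 0.12, 0.10, 0.12, 0.08,
        0.07, 0.06, 0.07, 0.06, 0.08, 0.07,
        0.35),
      c(1L, 1L, 1L, 0L, 0L, 0L,
        0L, 0L, 0L, 0L, 0L, 0L,
        0L, 1L, 1L, 1L, 1L, 1L,
        0L)),
    # blood-filled cyst: bilirubin-dominated with shared ceramide adducts
    cyst = prof(c(583.2562, 572.4815, 684.6067, 465.3044, 885.5499),
                c(1.00, 0.50, 0.30, 0.30, 0.20),
                c(0L, 1L, 1L, 0L, 0L))
  )
  regions <- list(
    list(label = "ovary", shape = "ellipse",
         params = c(2000, 2800, 1400, 1800), profile = "ovary"),
    list(label = "tumor", shape = "ellipse",
         params = c(5600, 2800, 1500, 1600), profile = "tumor"),
    list(label = "uterus", shape = "rect",
         params = c(1200, 5400, 6800, 8600), profile = "uterus"),
    list(label = "cyst", shape = "ellipse",
         params = c(2600, 10000, 1600, 1400), profile = "cyst")
  )
  phantom_spec(width_um = 8000, height_um = 12000,
               regions = regions, profiles = profiles,
               pixel_gain_sigma = pixel_gain_sigma,
               mz_jitter_sigma_at_ref = mz_jitter_sigma_at_ref,
               background_peak_rate = background_peak_rate,
               seed = seed)
}

region_mask <- function(rg, cx_um, cy_um) {
  # cx_um, cy_um: pixel-center coordinate matrices (rows x cols)
  p <- rg$params
  if (rg$shape == "ellipse") {
    ((cx_um - p[1]) / p[3])^2 + ((cy_um - p[2]) / p[4])^2 <= 1
  } else {
    cx_um >= p[1] & cx_um < p[3] & cy_um >= p[2] & cy_um < p[4]
  }
}

#' Rasterize a phantom spec into a ground-truth label image
#'
#' Every pixel carries exactly one region label; 0 is the off-tissue
#' background. A pixel belongs to a region if its center satisfies the
#' region's mask inequality. Overlapping regions with different profiles are
#' rejected.
#'
#' @param spec A [phantom_spec()].
#' @param pixel_pitch_um Pixel pitch in micrometers; must divide both
#'   `width_um` and `height_um`.
#' @return An object of class `phantom`: list with `label_image` (rows x cols
#'   integer matrix; row 1 = smallest y, col 1 = smallest x), `labels`
#'   (region label names indexed 1..n, background = 0), `profiles`,
#'   `pixel_pitch_um`, and the originating `spec`.
#' @export
make_phantom <- function(spec, pixel_pitch_um = 200) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_scalar_pos(pixel_pitch_um, "pixel_pitch_um")
  cols <- spec$width_um / pixel_pitch_um
  rows <- spec$height_um / pixel_pitch_um
  if (abs(cols - round(cols)) > 1e-9 || abs(rows - round(rows)) > 1e-9) {
    stop_("pixel_pitch_um (%g) must divide width (%g) and height (%g)",
          pixel_pitch_um, spec$width_um, spec$height_um)
  }
  cols <- as.integer(round(cols)); rows <- as.integer(round(rows))
  cx <- matrix(rep((seq_len(cols) - 0.5) * pixel_pitch_um, each = rows),
               nrow = rows)
  cy <- matrix(rep((seq_len(rows) - 0.5) * pixel_pitch_um, times = cols),
               nrow = rows)
  lab <- matrix(0L, rows, cols)
  owner <- matrix(NA_character_, rows, cols)
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    m <- region_mask(rg, cx, cy)
    clash <- m & lab != 0L
    if (any(clash)) {
      other <- spec$regions[[lab[which(clash)[1]]]]
      if (!identical(other$profile, rg$profile)) {
        stop_("regions '%s' and '%s' overlap but use different profiles ('%s' vs '%s')",
              other$label, rg$label, other$profile, rg$profile)
      }
      m <- m & lab == 0L  # same profile: first region keeps the pixels
    }
    lab[m] <- i
    owner[m] <- rg$label
  }
  structure(
    list(label_image = lab,
         labels = vapply(spec$regions, function(r) r$label, character(1)),
         profiles = spec$profiles,
         region_profile = vapply(spec$regions, function(r) r$profile, character(1)),
         pixel_pitch_um = pixel_pitch_um,
         rows = rows, cols = cols, spec = spec),
    class = "phantom"
  )
}

#' Simulate a comb-raster DESI acquisition over a phantom
#'
#' The stage traverses each line's first pass at constant velocity in +x,
#' with instantaneous flyback (no scans are emitted between passes). Scans
#' are emitted at `scan_period_s` intervals starting at each line's pass
#' start; each scan samples the phantom pixel under the stage position,
#' drawing that pixel's profile peaks scaled by a per-pixel lognormal gain,
#' adding Gaussian m/z jitter proportional to m/z, Poisson-count uniform
#' background peaks, and — for peaks with `n_chlorine >= 1` — an M+2
#' chlorine isotope partner at +1.99705 Th with intensity ratio 0.3196 per
#' chlorine.
#'
#' @param phantom A [make_phantom()] result.
#' @param acq List with `velocity_x_um_s` (default 160), `line_step_um`
#'   (default the phantom pixel pitch), `scan_period_s`, and optional
#'   `mz_range` for background peaks (default `c(400, 1000)`).
#' @param seed Seed; defaults to the phantom spec's seed.
#' @return List with `stream` (a `scan_stream`) and `track` (a `stage_track`).
#' @export
simulate_acquisition <- function(phantom,
                                 acq = list(velocity_x_um_s = 160,
                                            scan_period_s = 1.25),
                                 seed = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  spec <- phantom$spec
  v <- acq$velocity_x_um_s %||% 160
  step <- acq$line_step_um %||% phantom$pixel_pitch_um
  period <- acq$scan_period_s
  mz_range <- acq$mz_range %||% c(400, 1000)
  check_scalar_pos(v, "velocity_x_um_s")
  check_scalar_pos(period, "scan_period_s")
  check_scalar_pos(step, "line_step_um")
  if (abs(step - phantom$pixel_pitch_um) > 1e-9) {
    stop_("line_step_um (%g) must equal the phantom pixel pitch (%g)",
          step, phantom$pixel_pitch_um)
  }
  seed <- seed %||% spec$seed
  rows <- phantom$rows; cols <- phantom$cols
  width <- spec$width_um
  t_line <- width / v                      # first-pass traverse time, s
  n_scan <- as.integer(floor(t_line / period + 1e-12))
  if (n_scan < 1L) {
    stop_("scan_period_s (%g) too large: a %g um line at %g um/s receives zero scans",
          period, width, v)
  }
  flyback <- period  # instantaneous flyback modeled as a scan-free gap

  scans <- vector("list", rows * n_scan)
  times <- numeric(rows * n_scan)
  samp_t <- numeric(2 * rows); samp_x <- numeric(2 * rows); samp_y <- numeric(2 * rows)
  pw <- data.frame(line_index = seq_len(rows), t_start = NA_real_, t_end = NA_real_)

  with_seed(seed, {
    gain <- if (spec$pixel_gain_sigma > 0) {
      matrix(exp(rnorm(rows * cols, 0, spec$pixel_gain_sigma)), rows, cols)
    } else matrix(1, rows, cols)
    k <- 0L
    t0 <- 0
    for (l in seq_len(rows)) {
      y <- (l - 0.5) * step
      t_end <- t0 + t_line
      samp_t[2 * l - 1] <- t0;    samp_x[2 * l - 1] <- 0;     samp_y[2 * l - 1] <- y
      samp_t[2 * l]     <- t_end; samp_x[2 * l]     <- width; samp_y[2 * l]     <- y
      pw$t_start[l] <- t0; pw$t_end[l] <- t_end
      for (j in seq_len(n_scan) - 1L) {
        t <- t0 + j * period
        x <- v * j * period
        col <- min(cols, as.integer(floor(x / phantom$pixel_pitch_um)) + 1L)
        lb <- phantom$label_image[l, col]
        mzs <- numeric(0); ints <- numeric(0)
        if (lb != 0L) {
          pr <- spec$profiles[[phantom$region_profile[lb]]]
          g <- gain[l, col]
          base <- spec$base_intensity * pr$rel_intensity * g
          mzs <- pr$mz; ints <- base
          ncl <- pr$n_chlorine
          if (any(ncl >= 1L)) {
            mzs <- c(mzs, pr$mz[ncl >= 1L] + CL_M2_SPACING)
            ints <- c(ints, base[ncl >= 1L] * CL_M2_RATIO * ncl[ncl >= 1L])
          }
          if (spec$mz_jitter_sigma_at_ref > 0) {
            mzs <- mzs + rnorm(length(mzs),
                               0, (spec$mz_jitter_sigma_at_ref / 850) * mzs)
          }
        }
        if (spec$background_peak_rate > 0) {
          nb <- rpois(1, spec$background_peak_rate)
          if (nb > 0) {
            mzs <- c(mzs, runif(nb, mz_range[1], mz_range[2]))
            ints <- c(ints, rexp(nb, rate = 1 / (0.02 * spec$base_intensity)))
          }
        }
        o <- order(mzs)
        mzs <- mzs[o]; ints <- ints[o]
        if (length(mzs) > 1L) {  # enforce strictly increasing m/z
          keep <- c(TRUE, diff(mzs) > 0)
          if (!all(keep)) {
            ints <- as.vector(rowsum(ints, cumsum(keep)))
            mzs <- mzs[keep]
          }
        }
        k <- k + 1L
        times[k] <- t
        scans[[k]] <- list(time_s = t, mz = mzs, intensity = ints)
      }
      t0 <- t_end + flyback
    }
  })

  stream <- structure(list(scans = scans, times = times), class = "scan_stream")
  track <- structure(
    list(samples = data.frame(time_s = samp_t, x_um = samp_x, y_um = samp_y),
         velocity_x_um_s = v, line_step_um = step, pass_windows = pw),
    class = "stage_track")
  list(stream = stream, track = track)
}

#' @export
print.scan_stream <- function(x, ...) {
  np <- vapply(x$scans, function(s) length(s$mz), integer(1))
  cat(sprintf("<scan_stream> %d scans, %d peaks total, t in [%.3g, %.3g] s\n",
              length(x$scans), sum(np), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.stage_track <- function(x, ...) {
  cat(sprintf("<stage_track> %d lines, %g um/s, line step %g um\n",
              nrow(x$pass_windows), x$velocity_x_um_s, x$line_step_um))
  invisible(x)
}
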