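# Sparse image-cube construction from a scan stream + stage track, and the
# derived views (TIC image, extracted-ion images, ROI mean spectra).
#
# Conventions: pixels are stored row-major (pixel p = (row-1)*cols + col) in
# a sparse pixels x channels matrix V; row 1 = smallest y, col 1 = smallest
# x. Rendering row 1 at the top of a display is a plotting concern only.

# --- binning ----------------------------------------------------------------

# Deposit centroided peaks onto axis channels with a Gaussian window of sd
# sigma(m) = (ref_sigma/ref_mz)*m truncated at +/- 4 sigma and re-normalized
# to sum 1 over the retained channels, so binning preserves total intensity.
# Returns channel indices (i), values (x), the number of dropped out-of-range
# peaks and the total in-range intensity.
bin_peaks <- function(mz, intensity, axis) {
  stopifnot(inherits(axis, "mz_axis"), length(mz) == length(intensity))
  if (any(intensity < 0)) stop_("negative peak intensity")
  in_range <- mz >= axis$mz_lo & mz <= axis$mz_hi
  dropped <- sum(!in_range)
  mz <- mz[in_range]; intensity <- intensity[in_range]
  if (length(mz) == 0L) {
    return(list(i = integer(0), x = numeric(0), pk = integer(0),
                dropped = dropped, total_in = 0))
  }
  # sigma/bin-width is constant along the axis, so the half-window in
  # channels is one constant K for all peaks.
  K <- as.integer(ceiling(4 * axis$ref_sigma / axis$ref_bin_width)) + 1L
  jc <- round(log(mz / axis$mz_lo) / log1p(axis$r)) + 1
  offs <- seq.int(-K, K)
  jmat <- outer(as.integer(jc), offs, `+`)              # peaks x (2K+1)
  valid <- jmat >= 1L & jmat <= axis$n
  jcl <- pmin(pmax(jmat, 1L), axis$n)
  cmat <- matrix(axis$centers[jcl], nrow = length(mz))
  sig <- mz_sigma_at(axis, mz)
  d <- cmat - mz                                        # recycles by column
  w <- exp(-d^2 / (2 * sig^2))
  w[!valid | abs(d) > 4 * sig] <- 0
  wsum <- rowSums(w)
  if (any(wsum == 0)) {
    # a peak with no channel within 4 sigma cannot happen when sigma >= bin
    # width/8; guard for pathological axes by snapping to nearest channel
    z <- wsum == 0
    w[z, K + 1L] <- 1
    wsum[z] <- 1
  }
  val <- (w / wsum) * intensity
  keep <- w > 0
  # NB: matrix flattening is column-major; `pk` records which input peak
  # produced each triplet so callers can attribute them (e.g. to scans).
  list(i = as.integer(jcl[keep]), x = as.numeric(val[keep]),
       pk = as.integer(row(jcl)[keep]),
       dropped = dropped, total_in = sum(intensity))
}

#' Bin one centroided scan onto an m/z axis
#'
#' Each centroid (m, I) deposits `I * w_j` on channels j with
#' `|centers[j] - m| <= 4 sigma(m)`, `w_j` proportional to a Gaussian of sd
#' `sigma(m) = (ref_sigma/ref_mz) * m` and normalized so `sum_j w_j = 1`
#' (intensity preserving). Contributions from multiple centroids add.
#' Out-of-range peaks are dropped and counted in the `dropped` attribute.
#'
#' @param scan List with `mz` (strictly increasing) and `intensity`.
#' @param axis An [build_mz_axis()] axis.
#' @return A [Matrix::sparseVector] of length `axis$n` with attributes
#'   `dropped` (out-of-range peak count) and `total_in` (in-range intensity).
#' @export
bin_scan <- function(scan, axis) {
  stopifnot(inherits(axis, "mz_axis"))
  if (axis$n < 1L) stop_("empty m/z axis")
  b <- bin_peaks(scan$mz, scan$intensity, axis)
  agg <- rowsum(b$x, b$i)  # duplicate channels from adjacent peaks add
  v <- Matrix::sparseVector(x = as.numeric(agg),
                            i = as.integer(rownames(agg)), length = axis$n)
  attr(v, "dropped") <- b$dropped
  attr(v, "total_in") <- b$total_in
  v
}

# Bin a whole stream into a channels x n_scans sparse matrix in one
# vectorized pass (per-scan loops are too slow at phantom scale).
bin_stream <- function(stream, axis) {
  np <- vapply(stream$scans, function(s) length(s$mz), integer(1))
  mz <- unlist(lapply(stream$scans, `[[`, "mz"), use.names = FALSE)
  it <- unlist(lapply(stream$scans, `[[`, "intensity"), use.names = FALSE)
  scan_id <- rep.int(seq_along(stream$scans), np)
  in_range <- mz >= axis$mz_lo & mz <= axis$mz_hi
  dropped <- sum(!in_range)
  b <- bin_peaks(mz[in_range], it[in_range], axis)
  sid <- scan_id[in_range][b$pk]
  S <- Matrix::sparseMatrix(i = b$i, j = sid, x = b$x,
                            dims = c(axis$n, length(stream$scans)))
  attr(S, "dropped") <- dropped
  S
}

# --- pixel assignment -------------------------------------------------------

#' Assign first-pass scans to spatial positions and build the x grid
#'
#' Scans outside every first-pass window are discarded. Within a window the
#' stage x position at each scan time is linearly interpolated between the
#' bracketing track samples. A regular grid `x_g = x_min + g * pitch_x_um`
#' covers the traversed span (x_min is the smallest assigned x over all
#' lines, so line grids share one origin and pitch).
#'
#' @param track A `stage_track`.
#' @param scan_times Sorted vector of scan times (s).
#' @param pitch_x_um Grid pitch along x, in micrometers.
#' @return List with `assignment` (data.frame: `scan` index, `line_index`,
#'   `x_um`) and `grid_x` (numeric vector of grid x positions).
#' @export
assign_pixels <- function(track, scan_times, pitch_x_um) {
  stopifnot(inherits(track, "stage_track"))
  check_scalar_pos(pitch_x_um, "pitch_x_um")
  if (is.unsorted(scan_times)) stop_("scan_times must be sorted")
  pw <- track$pass_windows
  out <- vector("list", nrow(pw))
  for (i in seq_len(nrow(pw))) {
    sel <- which(scan_times >= pw$t_start[i] & scan_times <= pw$t_end[i])
    if (length(sel) < 2L) {
      stop_("line %d has %d scan(s) in its first-pass window [%g, %g]; need >= 2 for interpolation",
            pw$line_index[i], length(sel), pw$t_start[i], pw$t_end[i])
    }
    s <- track$samples
    in_line <- s$time_s >= pw$t_start[i] & s$time_s <= pw$t_end[i]
    x <- approx(s$time_s[in_line], s$x_um[in_line], xout = scan_times[sel],
                rule = 2)$y
    out[[i]] <- data.frame(scan = sel, line_index = pw$line_index[i], x_um = x)
  }
  assignment <- do.call(rbind, out)
  x_min <- min(assignment$x_um); x_max <- max(assignment$x_um)
  grid_x <- x_min + pitch_x_um * (0:floor((x_max - x_min) / pitch_x_um + 1e-9))
  list(assignment = assignment, grid_x = grid_x)
}

# Channel-wise linear interpolation of one line's binned scans onto grid_x.
# S: channels x n_scans sparse matrix (columns = scans of this line, ordered
# by x). Grid points outside the line's span become explicit zero pixels.
# Returns channels x length(grid_x) sparse matrix.
interp_line <- function(S, x_scan, grid_x) {
  ns <- length(x_scan)
  stopifnot(ncol(S) == ns, ns >= 2L)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  idx <- findInterval(grid_x, x_scan)
  for (g in seq_along(grid_x)) {
    k <- idx[g]
    if (k < 1L || grid_x[g] > x_scan[ns] + 1e-9) next  # outside span: zero pad
    if (k >= ns) {
      ti <- c(ti, ns); tj <- c(tj, g); tx <- c(tx, 1)
    } else {
      x0 <- x_scan[k]; x1 <- x_scan[k + 1]
      w <- if (x1 > x0) (grid_x[g] - x0) / (x1 - x0) else 0
      ti <- c(ti, k, k + 1L); tj <- c(tj, g, g); tx <- c(tx, 1 - w, w)
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(ns, length(grid_x)))
  S %*% A
}

#' Assemble gridded line spectra into a data cube
#'
#' @param line_spectra List (ordered by increasing y) of channels x
#'   n_grid sparse matrices sharing one [build_mz_axis()] axis and one
#'   aligned x grid. Ragged lines are padded with explicit zero pixels (a
#'   message reports how many).
#' @param axis The shared `mz_axis`.
#' @param pitch_x_um,pitch_y_um Pixel pitches in micrometers.
#' @param x0_um,y0_um Coordinates of pixel (1, 1) (defaults 0).
#' @return An object of class `msi_cube`: list with `rows`, `cols`, `axis`,
#'   pitches/origin, and `V`, the (rows*cols) x channels sparse non-negative
#'   pixel matrix in row-major pixel order.
#' @export
assemble_cube <- function(line_spectra, axis, pitch_x_um, pitch_y_um,
                          x0_um = 0, y0_um = 0) {
  stopifnot(length(line_spectra) >= 1L, inherits(axis, "mz_axis"))
  ncols <- vapply(line_spectra, ncol, integer(1))
  cols <- max(ncols)
  if (any(ncols < cols)) {
    message(sprintf("padding %d line(s) with zero pixels to %d columns",
                    sum(ncols < cols), cols))
    line_spectra <- lapply(line_spectra, function(S) {
      if (ncol(S) == cols) S
      else cbind(S, Matrix::Matrix(0, nrow(S), cols - ncol(S), sparse = TRUE))
    })
  }
  # each line contributes `cols` consecutive pixel rows (row-major order)
  V <- Matrix::t(do.call(cbind, line_spectra))
  V <- as(as(V, "CsparseMatrix"), "generalMatrix")
  structure(
    list(rows = length(line_spectra), cols = cols, axis = axis,
         pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
         x0_um = x0_um, y0_um = y0_um, V = V),
    class = "msi_cube")
}

#' Build a data cube from a scan stream and stage track
#'
#' End-to-end line-by-line cube construction: bin every scan onto `axis`,
#' keep first-pass scans, interpolate channel-wise onto a regular x grid,
#' and stack lines by increasing y.
#'
#' @param stream A `scan_stream`.
#' @param track A `stage_track`.
#' @param axis An [build_mz_axis()] axis.
#' @param pitch_x_um Grid pitch along x; default `velocity * median scan
#'   period` (square-ish pixels).
#' @return An `msi_cube`; attribute `dropped_peaks` counts out-of-range
#'   centroids.
#' @export
build_cube <- function(stream, track, axis, pitch_x_um = NULL) {
  stopifnot(inherits(stream, "scan_stream"), inherits(track, "stage_track"))
  if (is.null(pitch_x_um)) {
    period <- stats::median(diff(stream$times))
    pitch_x_um <- track$velocity_x_um_s * period
  }
  S <- bin_stream(stream, axis)
  ap <- assign_pixels(track, stream$times, pitch_x_um)
  lines <- split(ap$assignment, ap$assignment$line_index)
  ord <- order(as.numeric(names(lines)))
  line_spectra <- lapply(lines[ord], function(df) {
    o <- order(df$x_um)
    interp_line(S[, df$scan[o], drop = FALSE], df$x_um[o], ap$grid_x)
  })
  y0 <- min(track$samples$y_um)
  cube <- assemble_cube(line_spectra, axis, pitch_x_um, track$line_step_um,
                        x0_um = min(ap$grid_x), y0_um = y0)
  attr(cube, "dropped_peaks") <- attr(S, "dropped")
  cube
}

#' @export
print.msi_cube <- function(x, ...) {
  cat(sprintf(
    "<msi_cube> %d x %d pixels x %d channels, nnz %.4g%%, dense %d GB\n",
    x$rows, x$cols, x$axis$n, 100 * nnz_fraction(x),
    dense_storage_gb(x$rows, x$cols, x$axis$n)))
  invisible(x)
}

#' Fraction of nonzero elements in a cube
#' @param cube An `msi_cube`.
#' @return `nnz / (rows * cols * channels)`.
#' @export
nnz_fraction <- function(cube) {
  stopifnot(inherits(cube, "msi_cube"))
  length(cube$V@x) / (cube$rows * cube$cols * as.numeric(cube$axis$n))
}

#' Dense-equivalent storage of a cube shape, in binary GB
#'
#' @param rows,cols,channels Cube dimensions.
#' @param bytes_per_element Defaults to 8 (double precision).
#' @return `floor(rows * cols * channels * bytes / 2^30)` — e.g. 904 GB for
#'   the shape 805 x 59 x 2556741.
#' @export
dense_storage_gb <- function(rows, cols, channels, bytes_per_element = 8) {
  floor(as.numeric(rows) * cols * channels * bytes_per_element / 2^30)
}

#' Total ion current image
#' @param cube An `msi_cube`.
#' @return rows x cols matrix of per-pixel channel sums.
#' @export
tic_image <- function(cube) {
  stopifnot(inherits(cube, "msi_cube"))
  pixels_to_image(Matrix::rowSums(cube$V), cube$rows, cube$cols)
}

#' Extracted ion image
#'
#' Per-pixel sum of the channels whose centers lie in the closed window
#' `[target_mz - tol_mz, target_mz + tol_mz]`.
#'
#' @param cube An `msi_cube`.
#' @param target_mz Window center, Th.
#' @param tol_mz Half-width, Th.
#' @return rows x cols matrix.
#' @export
extracted_ion_image <- function(cube, target_mz, tol_mz) {
  stopifnot(inherits(cube, "msi_cube"))
  ctr <- cube$axis$centers
  sel <- which(ctr >= target_mz - tol_mz & ctr <= target_mz + tol_mz)
  if (length(sel) == 0L) {
    nearest <- ctr[which.min(abs(ctr - target_mz))]
    stop_("no channel center in [%g, %g]; nearest center is %.6f",
          target_mz - tol_mz, target_mz + tol_mz, nearest)
  }
  pixels_to_image(Matrix::rowSums(cube$V[, sel, drop = FALSE]),
                  cube$rows, cube$cols)
}

#' Region-of-interest selection
#'
#' @param mask Logical rows x cols matrix, or `NULL` to use an ellipse.
#' @param center,semi_axes Ellipse center `c(row, col)` and semi-axes
#'   `c(a_rows, b_cols)`, in pixels (used when `mask` is `NULL`).
#' @return Object of class `roi_selection`.
#' @export
roi_selection <- function(mask = NULL, center = NULL, semi_axes = NULL) {
  if (is.null(mask) && (is.null(center) || is.null(semi_axes))) {
    stop_("supply either a logical mask or ellipse center + semi_axes")
  }
  structure(list(mask = mask, center = center, semi_axes = semi_axes),
            class = "roi_selection")
}

roi_mask <- function(roi, rows, cols) {
  if (!is.null(roi$mask)) {
    stopifnot(is.logical(roi$mask), nrow(roi$mask) == rows,
              ncol(roi$mask) == cols)
    return(roi$mask)
  }
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  ((rr - roi$center[1]) / roi$semi_axes[1])^2 +
    ((cc - roi$center[2]) / roi$semi_axes[2])^2 <= 1
}

#' Mean spectrum over a region of interest
#'
#' @param cube An `msi_cube`.
#' @param roi An [roi_selection()] (mask or ellipse).
#' @return Numeric channel vector: the arithmetic mean of the selected
#'   pixels' spectra.
#' @export
roi_mean_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "msi_cube"), inherits(roi, "roi_selection"))
  m <- roi_mask(roi, cube$rows, cube$cols)
  px <- which(image_to_pixels(m))
  if (length(px) == 0L) stop_("ROI selects no pixels")
  as.numeric(Matrix::colMeans(cube$V[px, , drop = FALSE]))
}

#' Pixel matrix view of a cube
#'
#' @param cube An `msi_cube`.
#' @return The sparse (rows*cols) x channels matrix `V` with attribute
#'   `pixel_order = "row-major"`; reshaping any of its columns with the
#'   row-major convention reproduces the cube images exactly.
#' @export
pixel_matrix <- function(cube) {
  stopifnot(inherits(cube, "msi_cube"))
  V <- cube$V
  attr(V, "pixel_order") <- "row-major"
  V
}
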