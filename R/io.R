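# Plain-text, versioned container formats with exact round-trips. Floats
# are written with %.17g so read(write(x)) is bit-identical.

FMT_VERSION <- "1"

fmt_num <- function(x) sprintf("%.17g", x)

read_header_version <- function(lines, tag) {
  hdr <- strsplit(lines[1], " ")[[1]]
  if (length(hdr) < 3L || hdr[1] != "#desinmf" || hdr[2] != tag) {
    stop_("not a desinmf %s file (header: '%s')", tag, lines[1])
  }
  if (hdr[3] != FMT_VERSION) {
    stop_("%s container version mismatch: file has v%s, reader expects v%s",
          tag, hdr[3], FMT_VERSION)
  }
  invisible(TRUE)
}

#' Write / read a stage track as delimited text
#'
#' Three-column (time_s, x_um, y_um) tab-delimited samples with a commented
#' header carrying the acquisition geometry and first-pass windows.
#'
#' @param track A `stage_track`.
#' @param path Output file.
#' @return `write_stage_track`: the path, invisibly. `read_stage_track`:
#'   the reconstructed `stage_track`.
#' @export
write_stage_track <- function(track, path) {
  stopifnot(inherits(track, "stage_track"))
  pw <- track$pass_windows
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#desinmf stage_track %s", FMT_VERSION),
    sprintf("#velocity_x_um_s %s", fmt_num(track$velocity_x_um_s)),
    sprintf("#line_step_um %s", fmt_num(track$line_step_um)),
    sprintf("#pass_window %d %s %s", pw$line_index, fmt_num(pw$t_start),
            fmt_num(pw$t_end)),
    "time_s\tx_um\ty_um",
    sprintf("%s\t%s\t%s", fmt_num(track$samples$time_s),
            fmt_num(track$samples$x_um), fmt_num(track$samples$y_um))
  ), con)
  invisible(path)
}

#' @rdname write_stage_track
#' @export
read_stage_track <- function(path) {
  lines <- readLines(path)
  read_header_version(lines, "stage_track")
  meta <- lines[startsWith(lines, "#")]
  val <- function(key) {
    l <- meta[startsWith(meta, paste0("#", key, " "))]
    as.numeric(sub(paste0("#", key, " "), "", l, fixed = TRUE))
  }
  pw_lines <- meta[startsWith(meta, "#pass_window ")]
  pw <- do.call(rbind, lapply(strsplit(sub("#pass_window ", "", pw_lines), " "),
                              as.numeric))
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"))
  structure(
    list(samples = df,
         velocity_x_um_s = val("velocity_x_um_s"),
         line_step_um = val("line_step_um"),
         pass_windows = data.frame(line_index = as.integer(pw[, 1]),
                                   t_start = pw[, 2], t_end = pw[, 3])),
    class = "stage_track")
}

#' Write / read a scan stream as indexed text
#'
#' Layout: a commented header, a `scans` section (scan index, time_s,
#' n_peaks) and a `peaks` section (scan index, mz, intensity), both
#' tab-delimited. Empty scans are preserved via the scans section.
#'
#' @param stream A `scan_stream`.
#' @param path Output file.
#' @return `write_scan_stream`: the path, invisibly. `read_scan_stream`:
#'   the reconstructed `scan_stream`.
#' @export
write_scan_stream <- function(stream, path) {
  stopifnot(inherits(stream, "scan_stream"))
  np <- vapply(stream$scans, function(s) length(s$mz), integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#desinmf scan_stream %s", FMT_VERSION),
    "#section scans",
    sprintf("%d\t%s\t%d", seq_along(stream$scans), fmt_num(stream$times), np),
    "#section peaks",
    sprintf("%d\t%s\t%s",
            rep.int(seq_along(stream$scans), np),
            fmt_num(unlist(lapply(stream$scans, `[[`, "mz"), use.names = FALSE)),
            fmt_num(unlist(lapply(stream$scans, `[[`, "intensity"),
                           use.names = FALSE)))
  ), con)
  invisible(path)
}

#' @rdname write_scan_stream
#' @export
read_scan_stream <- function(path) {
  lines <- readLines(path)
  read_header_version(lines, "scan_stream")
  s1 <- which(lines == "#section scans")
  s2 <- which(lines == "#section peaks")
  scans_tab <- read.delim(text = paste(lines[(s1 + 1):(s2 - 1)], collapse = "\n"),
                          header = FALSE,
                          col.names = c("scan", "time_s", "n_peaks"))
  peaks_tab <- if (s2 < length(lines)) {
    read.delim(text = paste(lines[(s2 + 1):length(lines)], collapse = "\n"),
               header = FALSE, col.names = c("scan", "mz", "intensity"))
  } else data.frame(scan = integer(0), mz = numeric(0), intensity = numeric(0))
  scans <- vector("list", nrow(scans_tab))
  by_scan <- split(peaks_tab[c("mz", "intensity")], peaks_tab$scan)
  for (i in seq_len(nrow(scans_tab))) {
    p <- by_scan[[as.character(i)]]
    scans[[i]] <- list(time_s = scans_tab$time_s[i],
                       mz = if (is.null(p)) numeric(0) else p$mz,
                       intensity = if (is.null(p)) numeric(0) else p$intensity)
  }
  structure(list(scans = scans, times = scans_tab$time_s),
            class = "scan_stream")
}

#' Write / read a sparse data cube as a text container
#'
#' Header records dimensions, pitches, origin and the axis parameters (the
#' axis is rebuilt with [build_mz_axis()], whose construction is exactly
#' reproducible); the body holds the nonzero triplets (pixel, channel,
#' value) with pixel in row-major order.
#'
#' @param cube An `msi_cube`.
#' @param path Output file.
#' @return `write_cube`: the path, invisibly. `read_cube`: the
#'   reconstructed `msi_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "msi_cube"))
  trip <- Matrix::summary(cube$V)  # i = pixel, j = channel, x = value
  ax <- cube$axis
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#desinmf cube %s", FMT_VERSION),
    sprintf("#dims %d %d", cube$rows, cube$cols),
    sprintf("#pitch %s %s", fmt_num(cube$pitch_x_um), fmt_num(cube$pitch_y_um)),
    sprintf("#origin %s %s", fmt_num(cube$x0_um), fmt_num(cube$y0_um)),
    sprintf("#axis %s %s %s %s %s", fmt_num(ax$mz_lo), fmt_num(ax$mz_hi),
            fmt_num(ax$ref_mz), fmt_num(ax$ref_bin_width), fmt_num(ax$ref_sigma)),
    "pixel\tchannel\tvalue",
    sprintf("%d\t%d\t%s", trip$i, trip$j, fmt_num(trip$x))
  ), con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  read_header_version(lines, "cube")
  meta <- function(key) {
    l <- lines[startsWith(lines, paste0("#", key, " "))]
    as.numeric(strsplit(sub(paste0("#", key, " "), "", l, fixed = TRUE),
                        " ")[[1]])
  }
  dims <- meta("dims"); pitch <- meta("pitch"); origin <- meta("origin")
  axp <- meta("axis")
  axis <- build_mz_axis(axp[1], axp[2], axp[3], axp[4], axp[5])
  body <- lines[!startsWith(lines, "#")][-1]  # drop column header
  trip <- read.delim(text = paste(body, collapse = "\n"), header = FALSE,
                     col.names = c("pixel", "channel", "value"))
  V <- Matrix::sparseMatrix(i = trip$pixel, j = trip$channel, x = trip$value,
                            dims = c(dims[1] * dims[2], axis$n))
  structure(
    list(rows = as.integer(dims[1]), cols = as.integer(dims[2]), axis = axis,
         pitch_x_um = pitch[1], pitch_y_um = pitch[2],
         x0_um = origin[1], y0_um = origin[2], V = V),
    class = "msi_cube")
}

#' Write / read an annotated feature table
#'
#' Plain CSV preserving all columns including the serum-overlap flags.
#'
#' @param features data.frame.
#' @param path CSV path.
#' @return `write_feature_table`: the path, invisibly. `read_feature_table`:
#'   the data.frame.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a pixel image as tab-delimited text
#' @param img rows x cols matrix.
#' @param path Output file.
#' @export
write_image_txt <- function(img, path) {
  utils::write.table(img, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
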