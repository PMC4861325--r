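# End-to-end demo pipeline: phantom -> acquisition -> cube -> NMF / K-Means
# -> TIC / ion images / ROI spectrum -> annotation -> serum oPLS-DA, with
# every artifact written as delimited text plus a machine-readable summary.

#' Default pipeline configuration
#'
#' Nested sections mirror the module parameters. Every randomized stage
#' consumes an explicit seed derived from `seed`. Axis defaults for the
#' demo use a coarser bin width (0.015 Th at m/z 850) than the
#' high-resolution 0.0005 default of [build_mz_axis()] so the phantom cube
#' stays at ~5e4 channels.
#'
#' @param seed Global seed (stage seeds are derived by fixed offsets).
#' @param ... Named overrides for any top-level section (`phantom`, `acq`,
#'   `axis`, `nmf`, `kmeans`, `annotation`, `oplsda`, `serum`); unknown
#'   section or key names are rejected.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    phantom = list(pixel_gain_sigma = 0.25, mz_jitter_sigma_at_ref = 0.003,
                   background_peak_rate = 3, pixel_pitch_um = 200),
    acq = list(velocity_x_um_s = 160, scan_period_s = 0.625),
    axis = list(mz_lo = 400, mz_hi = 1000, ref_mz = 850,
                ref_bin_width = 0.015, ref_sigma = 0.03),
    nmf = list(ks = c(1L, 2L, 5L), tol = 1e-6, max_iter = 200L),
    kmeans = list(k = 5L, n_init = 10L, max_iter = 100L),
    annotation = list(cross_ref_tol = 0.005, cl_tol = 0.05,
                      major_peak_threshold = 5),
    oplsda = list(n_orth = 1L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) {
      stop_("unknown config section '%s' (known: %s)", nm,
            paste(names(cfg), collapse = ", "))
    }
    if (is.list(cfg[[nm]])) {
      for (key in names(dots[[nm]])) {
        if (!key %in% names(cfg[[nm]])) {
          stop_("unknown key '%s' in config section '%s' (known: %s)",
                key, nm, paste(names(cfg[[nm]]), collapse = ", "))
        }
        cfg[[nm]][[key]] <- dots[[nm]][[key]]
      }
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_("demo stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the end-to-end demo pipeline
#'
#' Simulates the default phantom acquisition, builds the sparse cube,
#' factorizes it with k = 1, 2 and 5 NMF components, runs the K-Means k = 5
#' baseline, extracts the TIC image, the tumor-ion extracted-ion images and
#' the tumor-ROI mean spectrum, annotates the bundled tumor-ion table
#' (theoretical masses, ppm errors, chloride-isotope verdicts on the ROI
#' spectrum, serum cross-reference), simulates the serum study and reports
#' leave-one-out oPLS-DA metrics. All artifacts are delimited text; a
#' `summary.json` captures the headline numbers and the fully resolved
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Report directory (created if missing).
#' @param phantom Optional pre-built [make_phantom()] phantom (defaults to
#'   the [default_phantom_spec()] phantom at the configured noise levels).
#' @param quiet Suppress progress messages (default FALSE).
#' @return The summary list, invisibly.
#' @export
run_demo <- function(config = pipeline_config(), out_dir,
                     phantom = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("stage phantom: generating tissue phantom + acquisition")
  ph <- run_stage("phantom", {
    if (is.null(phantom)) {
      spec <- default_phantom_spec(
        seed = seed,
        pixel_gain_sigma = config$phantom$pixel_gain_sigma,
        mz_jitter_sigma_at_ref = config$phantom$mz_jitter_sigma_at_ref,
        background_peak_rate = config$phantom$background_peak_rate)
      make_phantom(spec, config$phantom$pixel_pitch_um)
    } else phantom
  })
  sim <- run_stage("acquisition",
                   simulate_acquisition(ph, acq = config$acq, seed = seed + 1L))

  say("stage cube: binning %d scans", length(sim$stream$scans))
  axis <- run_stage("axis", do.call(build_mz_axis, config$axis))
  cube <- run_stage("cube", build_cube(sim$stream, sim$track, axis,
                                       pitch_x_um = config$phantom$pixel_pitch_um))
  say("  cube %d x %d x %d, nnz %.3g%%", cube$rows, cube$cols, axis$n,
      100 * nnz_fraction(cube))
  write_image_txt(tic_image(cube), file.path(out_dir, "tic_image.tsv"))

  V <- pixel_matrix(cube)
  nmf_fits <- list()
  for (k in config$nmf$ks) {
    say("stage nmf: k = %d", k)
    fit <- run_stage(sprintf("nmf_k%d", k),
                     nmf_als(V, k, seed = seed + 10L + k,
                             tol = config$nmf$tol,
                             max_iter = config$nmf$max_iter))
    nmf_fits[[as.character(k)]] <- fit
    norm <- normalize_component_set(fit, cube$rows, cube$cols)
    for (j in seq_len(k)) {
      write_image_txt(norm$images[[j]],
                      file.path(out_dir, sprintf("nmf_k%d_component%d_image.tsv",
                                                 k, j)))
    }
    utils::write.table(
      data.frame(iteration = seq_along(fit$objective_trace),
                 objective = fit$objective_trace),
      file.path(out_dir, sprintf("nmf_k%d_objective.tsv", k)),
      sep = "\t", row.names = FALSE)
  }

  say("stage kmeans: k = %d", config$kmeans$k)
  km <- run_stage("kmeans",
                  kmeans_segment(V, config$kmeans$k, seed = seed + 20L,
                                 n_init = config$kmeans$n_init,
                                 max_iter = config$kmeans$max_iter))
  write_image_txt(pixels_to_image(km$labels, cube$rows, cube$cols),
                  file.path(out_dir, "kmeans_labels.tsv"))

  say("stage annotation: tumor-ion table + ion images + ROI spectrum")
  tab <- run_stage("annotation", load_table1())
  for (i in seq_len(nrow(tab))) {
    img <- extracted_ion_image(cube, tab$exp_mz[i], tol_mz = 0.25)
    write_image_txt(img, file.path(out_dir,
                                   sprintf("ion_image_mz%.4f.tsv", tab$exp_mz[i])))
  }
  tumor_region <- ph$spec$regions[[which(vapply(ph$spec$regions, `[[`,
                                                character(1), "label") == "tumor")]]
  roi <- roi_selection(
    center = c(tumor_region$params[2] / ph$pixel_pitch_um,
               tumor_region$params[1] / ph$pixel_pitch_um),
    semi_axes = c(tumor_region$params[4] / ph$pixel_pitch_um,
                  tumor_region$params[3] / ph$pixel_pitch_um) * 0.8)
  roi_spec <- run_stage("roi", roi_mean_spectrum(cube, roi))
  utils::write.table(
    data.frame(mz = axis$centers[roi_spec > 0],
               intensity = roi_spec[roi_spec > 0]),
    file.path(out_dir, "tumor_roi_spectrum.tsv"), sep = "\t",
    row.names = FALSE)
  cl_checks <- lapply(which(tab$adduct == "[M+Cl]-"), function(i) {
    v <- tryCatch(chlorine_isotope_ratio(roi_spec, axis, tab$theo_mz[i],
                                         tol = config$annotation$cl_tol),
                  error = function(e) list(ratio = NA_real_, verdict = FALSE))
    data.frame(identity = tab$identity[i], mz = tab$theo_mz[i],
               m2_ratio = v$ratio, consistent_1cl = v$verdict)
  })
  cl_checks <- do.call(rbind, cl_checks)
  write.csv(cl_checks, file.path(out_dir, "chlorine_checks.csv"),
            row.names = FALSE)

  say("stage serum: simulate + LOO oPLS-DA")
  serum <- run_stage("serum",
                     simulate_serum(serum_spec(seed = seed + 30L)))
  tab <- run_stage("cross_reference",
                   cross_reference(tab, tab$exp_mz[tab$serum_detected],
                                   tol_mz = config$annotation$cross_ref_tol))
  write_feature_table(tab, file.path(out_dir, "annotation_table.csv"))
  loo <- run_stage("oplsda",
                   loo_cross_validate(serum$matrix, serum$labels,
                                      n_orth = config$oplsda$n_orth))
  fit_full <- run_stage("oplsda_fit",
                        opls_da_fit(serum$matrix, serum$labels,
                                    n_orth = config$oplsda$n_orth))

  dd <- dedupe_metabolites(tab)
  rel_err <- vapply(nmf_fits, nmf_relative_error, numeric(1), V = V)
  summary <- list(
    config = unclass(config),
    cube = list(rows = cube$rows, cols = cube$cols, channels = axis$n,
                nnz_fraction = nnz_fraction(cube),
                dense_gb = dense_storage_gb(cube$rows, cube$cols, axis$n),
                dropped_peaks = attr(cube, "dropped_peaks")),
    nmf = list(relative_error = as.list(rel_err),
               iterations = lapply(nmf_fits, `[[`, "iterations")),
    kmeans = list(inertia = km$inertia,
                  cluster_sizes = as.integer(table(factor(km$labels,
                                                          levels = 1:km$k)))),
    annotation = list(n_ions = dd$n_ions, n_metabolites = dd$n_metabolites,
                      n_serum_overlap = sum(tab$serum_overlap),
                      max_abs_ppm_recomputed = max(tab$ppm)),
    chlorine = list(n_checked = nrow(cl_checks),
                    n_consistent = sum(cl_checks$consistent_1cl)),
    oplsda = list(accuracy = loo$accuracy, sensitivity = loo$sensitivity,
                  specificity = loo$specificity,
                  n_misclassified = loo$n_misclassified,
                  n_lv = fit_full$n_lv,
                  var_x_percent = fit_full$var_x_percent,
                  var_y_percent = fit_full$var_y_percent)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(summary)
}
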