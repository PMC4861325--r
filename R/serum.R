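# Synthetic serum feature matrices emulating a UPLC-MS case/control study
# (early-stage tumor vs control mice).

#' Define a synthetic serum study
#'
#' @param n_case,n_control Sample counts (default 14 early-tumor vs 11
#'   control, the curated UPLC-MS comparison design).
#' @param features data.frame with columns `feature_id`, `log2_fold_change`
#'   (case vs control), `base_abundance` (control geometric mean, arbitrary
#'   peak-area units) and `lognormal_sigma` (sd of log abundance). Default:
#'   8 features, 6 lower and 2 higher in cases (|log2fc| >= 1), sigma 0.2.
#' @param seed Integer seed.
#' @return An object of class `serum_spec`.
#' @export
serum_spec <- function(n_case = 14L, n_control = 11L,
                       features = default_serum_features(),
                       seed = 1L) {
  if (n_case < 2L || n_control < 2L) stop_("need >= 2 samples per class")
  stopifnot(is.data.frame(features),
            all(c("feature_id", "log2_fold_change", "base_abundance",
                  "lognormal_sigma") %in% names(features)))
  if (any(features$lognormal_sigma <= 0)) stop_("lognormal_sigma must be > 0")
  if (any(features$base_abundance <= 0)) stop_("base_abundance must be > 0")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 features = features, seed = as.integer(seed)),
            class = "serum_spec")
}

#' Default serum feature panel
#'
#' Eight features mirroring the tissue/serum overlap panel: six measured in
#' lower abundance in early-tumor sera and two (Cer(d34:1), LPI(18:0)) in
#' higher abundance, all with |log2 fold change| >= 1 and lognormal sigma 0.2.
#'
#' @param sigma Lognormal sigma applied to every feature (default 0.2).
#' @param lfc_scale Multiplier on the default log2 fold changes (default 1).
#' @return data.frame suitable for [serum_spec()].
#' @export
default_serum_features <- function(sigma = 0.2, lfc_scale = 1) {
  data.frame(
    feature_id = c("mz436.2826", "mz465.3054", "mz480.3091", "mz524.2975",
                   "mz583.2567", "mz737.5318", "mz536.5044", "mz599.3209"),
    log2_fold_change = lfc_scale *
      c(-1.2, -1.5, -1.1, -1.3, -1.4, -1.0, 1.2, 1.1),
    base_abundance = c(2.1e5, 8.4e4, 1.3e5, 5.0e4, 3.2e5, 7.5e4, 1.8e5, 6.2e4),
    lognormal_sigma = sigma
  )
}

#' Simulate a serum feature matrix
#'
#' Case abundances are lognormal with meanlog `log(base) + log2fc * log(2)`;
#' controls are lognormal with meanlog `log(base)`; both use the feature's
#' `lognormal_sigma`. Generation is a pure function of (spec, seed).
#'
#' @param spec A [serum_spec()].
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @return List with `matrix` (samples x features, rownames `ET_*` /
#'   `control_*`) and `labels` (factor with levels `control`, `ET`; ET =
#'   early-stage tumor).
#' @export
simulate_serum <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "serum_spec"))
  seed <- seed %||% spec$seed
  f <- spec$features
  n <- spec$n_case + spec$n_control
  labels <- factor(rep(c("ET", "control"), c(spec$n_case, spec$n_control)),
                   levels = c("control", "ET"))
  m <- with_seed(seed, {
    mu <- outer(as.numeric(labels == "ET"), f$log2_fold_change * log(2)) +
      matrix(log(f$base_abundance), n, nrow(f), byrow = TRUE)
    matrix(exp(mu + rnorm(n * nrow(f)) *
                 matrix(f$lognormal_sigma, n, nrow(f), byrow = TRUE)),
           n, nrow(f))
  })
  dimnames(m) <- list(
    c(paste0("ET_", seq_len(spec$n_case)),
      paste0("control_", seq_len(spec$n_control))),
    f$feature_id)
  list(matrix = m, labels = labels)
}
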