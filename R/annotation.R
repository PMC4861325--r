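# Adduct-mass annotation: elemental formula parsing, monoisotopic masses,
# theoretical adduct m/z and ppm errors, chloride-isotope verification,
# major-peak listing, metabolite deduplication and tissue/serum
# cross-referencing.

# Monoisotopic atomic masses (u), most abundant isotope, 10 significant
# digits; 12C is exact by definition of the unified scale.
ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Cl = 34.96885268
)
PROTON_MASS <- 1.00727646
ELECTRON_MASS <- 0.00054858

#' Parse an elemental formula
#'
#' Accepts plain Hill-style strings (`"C33H36N4O6"`) and the underscored
#' dialect used in annotation tables (`"C_33_H_36_N_4_O_6"`). Supported
#' elements: C, H, N, O, P, S, Cl.
#'
#' @param text Formula string.
#' @return Named integer vector of element counts, class `elemental_formula`.
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop_("formula must be a non-empty string")
  }
  s <- gsub("_", "", text)
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(s)) {
    m <- regmatches(substr(s, pos, nchar(s)),
                    regexpr("^([A-Z][a-z]?)([0-9]*)",
                            substr(s, pos, nchar(s))))
    if (length(m) == 0 || !nzchar(m)) {
      stop_("malformed formula '%s' at position %d ('%s')", text, pos,
            substr(s, pos, pos))
    }
    el <- sub("^([A-Z][a-z]?).*$", "\\1", m)
    if (!el %in% names(ATOMIC_MASS)) {
      stop_("unsupported element '%s' in formula '%s' at position %d",
            el, text, pos)
    }
    num <- sub("^[A-Z][a-z]?", "", m)
    n <- if (nzchar(num)) as.integer(num) else 1L
    prev <- if (el %in% names(counts)) counts[[el]] else 0L
    counts[el] <- prev + n
    pos <- pos + nchar(m)
  }
  if (sum(counts) < 1L) stop_("formula '%s' has no atoms", text)
  structure(counts, class = "elemental_formula")
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula An [parse_formula()] result, or a formula string.
#' @return Mass in Da (sum of most-abundant-isotope masses).
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(ATOMIC_MASS[names(formula)] * as.integer(formula))
}

#' Adduct definition
#'
#' Supported singly charged negative adducts: `[M-H]-` (proton removal,
#' delta = -1.00727646) and `[M+Cl]-` (chloride attachment, delta =
#' +34.96885268 + electron mass 0.00054858).
#'
#' @param name `"[M-H]-"` or `"[M+Cl]-"`.
#' @return Object of class `adduct_spec` with `name`, `mass_delta` (Th) and
#'   `charge` (-1).
#' @export
adduct_spec <- function(name) {
  delta <- switch(name,
    "[M-H]-" = -PROTON_MASS,
    "[M+Cl]-" = ATOMIC_MASS[["Cl"]] + ELECTRON_MASS,
    stop_("unsupported adduct '%s' (supported: [M-H]-, [M+Cl]-)", name))
  structure(list(name = name, mass_delta = delta, charge = -1L),
            class = "adduct_spec")
}

#' Theoretical m/z of a neutral formula under an adduct
#'
#' Full-precision value; round to 4 decimals for reporting (see
#' [round4()]). ppm errors are computed against this unrounded value.
#'
#' @param neutral_formula Neutral-molecule formula (string or
#'   `elemental_formula`).
#' @param adduct `"[M-H]-"`, `"[M+Cl]-"` or an [adduct_spec()].
#' @return Theoretical m/z in Th.
#' @export
theoretical_mz <- function(neutral_formula, adduct) {
  if (is.character(neutral_formula)) neutral_formula <- parse_formula(neutral_formula)
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  if (adduct$name == "[M-H]-" &&
      (is.na(neutral_formula["H"]) || neutral_formula["H"] < 1L)) {
    stop_("[M-H]- requires at least one H in the neutral formula")
  }
  monoisotopic_mass(neutral_formula) + adduct$mass_delta
}

#' Round to 4 decimals (reporting convention for theoretical m/z)
#' @param x Numeric.
#' @export
round4 <- function(x) round(x, 4)

#' Relative mass error in ppm
#'
#' `|exp - theo| / theo * 1e6`, reported rounded to 1 decimal. The
#' theoretical mass is used at full precision (rounding it to 4 decimals
#' first shifts several published table values by 0.1 ppm).
#'
#' @param exp_mz Experimental m/z, Th.
#' @param theo_mz Theoretical m/z, Th (> 0).
#' @return ppm error, 1 decimal.
#' @export
ppm_error <- function(exp_mz, theo_mz) {
  if (any(theo_mz <= 0)) stop_("theo_mz must be > 0")
  round(abs(exp_mz - theo_mz) / theo_mz * 1e6, 1)
}

#' Convert a published ion-formula row to a neutral formula
#'
#' Annotation tables mix ion formulas (most rows) and neutral formulas
#' (e.g. cholesterol sulfate, bilirubin). The package's canonical input is
#' the neutral formula plus an adduct; this helper converts: for `[M-H]-`
#' add one H, for `[M+Cl]-` drop one Cl (a `[M+Cl]-` row whose formula has
#' no Cl is already neutral).
#'
#' @param formula Formula string as printed.
#' @param adduct Adduct name.
#' @param formula_is_neutral Set TRUE when the printed formula is already
#'   the neutral molecule.
#' @return `elemental_formula` of the neutral molecule.
#' @export
ion_formula_to_neutral <- function(formula, adduct,
                                   formula_is_neutral = FALSE) {
  f <- parse_formula(formula)
  if (formula_is_neutral) return(f)
  if (adduct == "[M-H]-") {
    f["H"] <- (if (is.na(f["H"])) 0L else f["H"]) + 1L
  } else if (adduct == "[M+Cl]-") {
    if (is.na(f["Cl"]) || f["Cl"] < 1L) return(f)  # printed neutral
    f["Cl"] <- f["Cl"] - 1L
    f <- f[f > 0L]
  } else {
    stop_("unsupported adduct '%s'", adduct)
  }
  structure(f, class = "elemental_formula")
}

#' Annotate experimental features with theoretical masses and ppm errors
#'
#' @param features data.frame with columns `exp_mz`, `formula` (as printed;
#'   ion or neutral), `adduct`, `identity`, and optionally
#'   `formula_is_neutral` (logical) and `serum_detected`.
#' @return The input with added columns `neutral_formula` (canonical
#'   string), `theo_mz` (rounded to 4 decimals), `theo_mz_full` and
#'   `ppm` (1 decimal).
#' @export
annotate_features <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("exp_mz", "formula", "adduct", "identity") %in%
                  names(features)))
  fin <- features$formula_is_neutral %||% rep(FALSE, nrow(features))
  neutral <- character(nrow(features)); theo <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    nf <- ion_formula_to_neutral(features$formula[i], features$adduct[i],
                                 fin[i])
    neutral[i] <- format_formula(nf)
    theo[i] <- theoretical_mz(nf, features$adduct[i])
  }
  features$neutral_formula <- neutral
  features$theo_mz_full <- theo
  features$theo_mz <- round4(theo)
  features$ppm <- ppm_error(features$exp_mz, theo)
  features
}

format_formula <- function(f) {
  ord <- c("C", "H", intersect(c("N", "O", "P", "S", "Cl"), names(f)))
  ord <- ord[ord %in% names(f)]
  paste0(vapply(ord, function(el) {
    if (f[el] == 1L) el else paste0(el, f[el])
  }, character(1)), collapse = "")
}

#' Chlorine M+2 isotope check on a binned spectrum
#'
#' Compares the windowed intensity at `base_mz + 1.99705` (37Cl - 35Cl) to
#' the windowed intensity at `base_mz`. A ratio within `[0.24, 0.40]`
#' (0.3196 +/- 25%, the 24.22/75.77 isotope abundance ratio the "3:1"
#' argument rests on) is consistent with one chlorine atom.
#'
#' @param spectrum Channel intensity vector on `axis`.
#' @param axis The [build_mz_axis()] axis.
#' @param base_mz Base (35Cl) peak m/z, Th.
#' @param tol Window half-width, Th (default 0.02).
#' @return List with `ratio` (M+2 / M) and `verdict` (`TRUE` when
#'   consistent with 1 Cl).
#' @export
chlorine_isotope_ratio <- function(spectrum, axis, base_mz, tol = 0.02) {
  stopifnot(inherits(axis, "mz_axis"), length(spectrum) == axis$n)
  win <- function(m) {
    sel <- axis$centers >= m - tol & axis$centers <= m + tol
    sum(spectrum[sel])
  }
  base <- win(base_mz)
  if (base <= 0) stop_("no base peak found within %g of m/z %.4f", tol, base_mz)
  m2 <- win(base_mz + CL_M2_SPACING)
  ratio <- m2 / base
  list(ratio = ratio, verdict = ratio >= 0.24 && ratio <= 0.40)
}

#' List major peaks of a spectrum
#'
#' Local maxima of the binned spectrum, grouped within one local bin width,
#' expressed as percent of the base peak and filtered at
#' `>= threshold_percent`.
#'
#' @param spectrum Channel intensity vector on `axis`.
#' @param axis The [build_mz_axis()] axis.
#' @param threshold_percent Relative-abundance cutoff (default 5).
#' @return data.frame with `mz` (channel center of the group maximum) and
#'   `rel_percent`, sorted by m/z.
#' @export
list_major_peaks <- function(spectrum, axis, threshold_percent = 5) {
  stopifnot(inherits(axis, "mz_axis"), length(spectrum) == axis$n)
  if (all(spectrum == 0)) stop_("all-zero spectrum")
  x <- as.numeric(spectrum)
  n <- length(x)
  left <- c(-Inf, x[-n]); right <- c(x[-1], -Inf)
  is_max <- x > 0 & x >= left & x > right
  idx <- which(is_max)
  if (length(idx) > 1L) {
    # group maxima closer than one local bin width; keep the tallest
    grp <- cumsum(c(TRUE, diff(axis$centers[idx]) >
                      mz_bin_width_at(axis, axis$centers[idx[-1]])))
    idx <- vapply(split(idx, grp), function(ii) ii[which.max(x[ii])],
                  integer(1))
  }
  rel <- x[idx] / max(x) * 100
  keep <- rel >= threshold_percent
  out <- data.frame(mz = axis$centers[idx[keep]], rel_percent = rel[keep])
  out[order(out$mz), , drop = FALSE]
}

#' Deduplicate annotated ions into metabolites
#'
#' Groups features by identity label; a multi-candidate label such as
#' `"LPE(O-18:1), LPE(P-18:0)"` counts as one group.
#'
#' @param features data.frame with an `identity` column (e.g. from
#'   [annotate_features()] or [load_table1()]).
#' @return List with `n_ions`, `n_metabolites` and `groups` (named list of
#'   row indices per identity).
#' @export
dedupe_metabolites <- function(features) {
  if (is.null(features) || nrow(features) == 0L) {
    return(list(n_ions = 0L, n_metabolites = 0L, groups = list()))
  }
  groups <- split(seq_len(nrow(features)), features$identity)
  list(n_ions = nrow(features), n_metabolites = length(groups),
       groups = groups)
}

#' Cross-reference tissue features against serum m/z values
#'
#' A tissue feature matches when any serum m/z lies within `tol_mz` of its
#' experimental m/z.
#'
#' @param tissue data.frame with an `exp_mz` column.
#' @param serum_mz Numeric vector of serum feature m/z values.
#' @param tol_mz Tolerance in Th (default 0.005).
#' @return The `tissue` data.frame with `serum_overlap` (logical) and
#'   `serum_delta_mz` (signed serum - tissue difference of the closest
#'   match, NA when unmatched) columns; attribute `n_overlap` gives the
#'   match count.
#' @export
cross_reference <- function(tissue, serum_mz, tol_mz = 0.005) {
  check_scalar_pos(tol_mz, "tol_mz")
  stopifnot(is.data.frame(tissue), "exp_mz" %in% names(tissue))
  overlap <- logical(nrow(tissue)); delta <- rep(NA_real_, nrow(tissue))
  for (i in seq_len(nrow(tissue))) {
    if (length(serum_mz) == 0L) break
    d <- serum_mz - tissue$exp_mz[i]
    j <- which.min(abs(d))
    if (abs(d[j]) <= tol_mz) {
      overlap[i] <- TRUE
      delta[i] <- d[j]
    }
  }
  tissue$serum_overlap <- overlap
  tissue$serum_delta_mz <- delta
  attr(tissue, "n_overlap") <- sum(overlap)
  tissue
}

#' Load the bundled tumor-ion annotation table
#'
#' An 18-row fixture transcribing the published tumor-component ion list:
#' experimental m/z, printed formula (ion or neutral), adduct, printed
#' theoretical m/z and ppm (kept verbatim for reference; see the `note`
#' column for printed-value discrepancies), identity label and the
#' serum-detection flag.
#'
#' @param annotated Recompute theoretical masses and ppm errors via
#'   [annotate_features()] (default TRUE).
#' @return data.frame with 18 rows.
#' @export
load_table1 <- function(annotated = TRUE) {
  path <- system.file("extdata", "tumor_ions_table.csv", package = "desinmf",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$formula_is_neutral <- as.logical(df$formula_is_neutral)
  df$serum_detected <- as.logical(df$serum_detected)
  if (annotated) df <- annotate_features(df)
  df
}
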