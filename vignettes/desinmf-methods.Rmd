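---
title: "Methods: sparse MSI cubes, ALS-NMF segmentation and adduct annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse MSI cubes, ALS-NMF segmentation and adduct annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desinmf)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic generators do
and do not emulate, the numerical conventions, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite or the demo pipeline does not itself compute.

## 1. From raster acquisition to a sparse data cube

**Acquisition model.** A DESI stage moves the sample under a stationary
sprayer along a comb-shaped path: constant-velocity passes in +x
(default 160 µm s⁻¹), stepped by 200 µm in y between lines. Only the
first pass of each line carries scans; flyback is modeled as
instantaneous (a scan-free gap), the simplest model consistent with
first-pass-only cube construction. The mass spectrometer emits centroided
negative-mode scans (m/z 400–1000) at a fixed scan period. The instrument
scan period is not a published constant, so it is an explicit parameter
(`scan_period_s`); the worked defaults use 0.625 s, i.e. two scans per
200 µm pixel.

**Common m/z axis.** All scans share one logarithmically spaced axis with
constant *relative* spacing `r = ref_bin_width / ref_mz`:
`centers[j] = mz_lo * (1 + r)^(j-1)`, giving a local bin width `r·m` —
0.0005 Th at m/z 850 for the defaults. The channel count is
`ceiling(log(mz_hi/mz_lo) / log1p(r))`, which for (400, 1000, 0.0005 @ 850)
is 1,557,695. The deposition width σ is quoted at the same reference mass
and scales identically (`σ(m) = (ref_sigma/ref_mz)·m`), so σ/bin-width is
constant along the axis; quoting both "at m/z 850" leaves the scaling
ambiguous, and proportional scaling is the choice that keeps the
smoothing kernel shape identical in units of bins everywhere.

**Binning.** Each centroid (m, I) deposits `I·w_j` on the channels within
4σ(m) of m, with Gaussian weights renormalized to `Σ w_j = 1`. Truncation
radius and renormalization are not published details; they were chosen so
binning **conserves intensity exactly**, which is what makes TIC images
and ROI averages meaningful. Out-of-range centroids are dropped and
counted, not clamped, matching the fixed acquisition range. The candidate
window is `±(ceiling(4σ/bin) + 1)` channels, which always covers the 4σ
support because σ/bin-width is constant.

**Pixel assignment and interpolation.** Scan x positions are linearly
interpolated from the stage track inside each first-pass window; a
regular grid `x_g = x_min + g·pitch` with a single global origin covers
the traversed span, and each grid spectrum is the channel-wise linear
interpolation of the two bracketing scans. Binning and interpolation are
both linear, so their order is immaterial within a scan pair; the package
bins first because it keeps the interpolation sparse. The x pitch
defaults to velocity × median scan period (square-ish pixels) and the y
pitch to the line step; neither is a published constant. Pixels are
stored row-major (`p = (row-1)·cols + col`, row 1 = smallest y); whether
row 1 renders at the top is a display concern only.

**Sparsity.** The cube is a `Matrix::dgCMatrix` of pixels × channels.
`dense_storage_gb()` documents the dense-equivalent cost (904 binary GB
for 805 × 59 × 2,556,741 at 8 bytes/element); `nnz_fraction()` is
re-counted densely in tests on small cubes to keep the accounting honest.

## 2. ALS-NMF segmentation

Given the pixel matrix **V** (pixels × channels, non-negative), NMF finds
**W** (pixels × k, component images) and **H** (k × channels, component
spectra) minimizing `D = ½‖V − WH‖²_F`. The algorithm is alternating
least squares exactly as classically stated: initialize H with positive
values, then repeat

```
W <- V Hᵀ (H Hᵀ)^#   ;  W[W < 0] <- 0
H <- (Wᵀ W)^# Wᵀ V   ;  H[H < 0] <- 0
```

until the relative objective change falls below `tol` (default 1e-6,
`max_iter` 500). Implementation decisions, each taken where the published
description is silent:

* **Initialization.** H ~ i.i.d. uniform on [0.1, 1] from the seeded
  generator — positive and bounded away from zero so no row is born dead.
  Results are a pure function of (V, k, seed).
* **Pseudoinverse.** SVD-based, singular values below `1e-12·σ_max`
  treated as zero. The k × k Gram matrices `HHᵀ`/`WᵀW` can become
  rank-deficient after clamping; hard inversion would blow up.
* **Dead components.** A component whose image column (or spectrum row)
  becomes all-zero is re-seeded once from the generator, then left zero
  with a message if it dies again.
* **Monotonicity.** ALS *with clamping* is not provably monotone per
  iteration. The tests assert end ≤ start and that no iteration increases
  D by more than 1 % of its current value on the test corpus; the exact
  objective is computed sparsely as
  `½(‖V‖² − 2·tr(HᵀWᵀV) + tr((WᵀW)(HHᵀ)))`.
* **No normalization of V.** NMF sees the raw binned intensities; any
  scaling is the caller's decision.
* **Scale indeterminacy.** (W, H) is only defined up to a diagonal
  rescaling, so tests compare reconstruction products, normalized
  components, or correlations — never raw factors.

For display, component spectra are normalized jointly so that the single
largest peak across the whole component set reads 100 % (the set base
peak), preserving all between-spectrum ratios; component images are
min-max scaled individually. `component_assignment()` quantifies the
usual visual component-vs-anatomy comparison by greedy one-to-one
matching on Pearson correlation against region indicators.

At k = 1 the clamping is inactive at the optimum (the leading singular
pair of a non-negative matrix is non-negative), so ALS must match the
rank-1 truncated-SVD error — the strongest available exact oracle, and an
acceptance criterion at relative 1e-6 over 20 random matrices.

## 3. K-Means baseline

`kmeans_segment()` is a deliberate re-implementation rather than
`stats::kmeans`: the contract needs seeded k-means++ initialization,
best-of-`n_init` restarts, and an inertia trace whose monotonicity is
asserted. Distances are Euclidean on the same unnormalized V given to
NMF so the two methods see identical input (the original preprocessing is
unreported; this substitute is explicit, not a reconstruction). For
overlap bookkeeping, soft NMF component images are binarized at their
Otsu threshold — parameter-free and documented — while K-Means labels
stay hard; `compare_segmentations()` keeps the two kinds distinct, since
a hard cluster is a strictly less informative descriptor than a soft
component image.

## 4. Adduct masses, ppm errors, isotopes

Monoisotopic masses use embedded constants (C 12 exact, H 1.00782503207,
N 14.0030740048, O 15.9949146196, P 30.97376163, S 31.97207100,
Cl 34.96885268). Anion m/z includes the electron mass:
`[M−H]⁻ = M − 1.00727646`, `[M+Cl]⁻ = M + 34.96885268 + 0.00054858`.

Published feature tables of this kind mix **ion** formulas (most rows)
and **neutral** formulas (cholesterol sulfate, bilirubin, and one
sphingomyelin row printed without its adduct chlorine). The package's
canonical input is the neutral formula plus an adduct;
`ion_formula_to_neutral()` absorbs the inconsistency (add one H for
[M−H]⁻; drop one Cl for [M+Cl]⁻; a Cl-free [M+Cl]⁻ formula is already
neutral). The bundled 18-row fixture (`load_table1()`) transcribes the
printed values verbatim — including both variants of the Cer(d42:1)+Cl
theoretical mass that appear in the source (684.6061 in the table,
684.6067 in the text; computation matches the text) — and carries a
`note` column cataloguing each printed value that does not follow from
the printed formula under the constants above. Those discrepancies are
recorded, not forced.

**ppm convention.** `ppm_error(exp, theo) = |exp − theo|/theo × 1e6`,
rounded to one decimal, with `theo` at **full precision**. Computing ppm
against the 4-decimal-rounded theoretical mass instead shifts several
published values by 0.1 ppm (e.g. Cer(d42:2)+Cl becomes 2.8 rather than
the published 2.9); the full-precision convention reproduces all four
ppm values used in acceptance (2.1, 7.0, 3.6, 2.9). Theoretical masses
are rounded to 4 decimals for display only.

**Chlorine check.** A single chlorine shows an M+2 isotopologue at
+1.99705 Th (³⁷Cl−³⁵Cl) with abundance ratio 24.22/75.77 = 0.3196 — the
"3:1" argument. `chlorine_isotope_ratio()` compares windowed intensities
and calls the verdict for ratios within 0.3196 ± 25 % ([0.24, 0.40]), a
band wide enough for binning and gain noise but far from the ~1:1
ambiguity of overlapping species.

**Cross-referencing** uses ±0.005 Th by default (no tolerance is
published; 0.005 Th is ~10 ppm at m/z 500, a conventional
accurate-mass match window), and metabolite deduplication groups rows by
identity label, counting a multi-candidate label as one metabolite —
which is precisely how 18 ions collapse to 15 metabolites in the fixture
(three ceramides each appear as both [M−H]⁻ and [M+Cl]⁻).

## 5. oPLS-DA with leave-one-out cross-validation

The original analysis used a commercial toolbox; the package implements
the standard orthogonal-signal-correction form for a single response:
autoscale X (the common toolbox default; `scale = "center"` switches to
mean-centering), code y ∈ {0, 1} and center; predictive weight
`w ∝ Xᵀy` (unit norm); each orthogonal component's weight is the
X-loading of the predictive score minus its projection on w, normalized,
and its variation `t_o p_oᵀ` is deflated from X; a final one-component
PLS on the filtered matrix gives scores, loading, and regression scalar.
Orthogonal scores have zero covariance with y by construction (asserted
at 1e-10). Captured X variance sums the predictive and orthogonal
`t pᵀ` sums of squares over ‖X‖² — the sequential deflations are mutually
orthogonal, so this equals the brute-force
`1 − ‖X − reconstruction‖²/‖X‖²` (tested at 1e-8); captured Y variance is
`‖t b‖²/‖y_c‖²`. Defaults mirror the conventional 2-LV model
(1 predictive + 1 orthogonal). Prediction thresholds the predicted class
code at the midpoint 0.5, with exact ties assigned to the control class;
the tumor group (ET) is the positive class for sensitivity. Fitting is
deterministic; LOO refits on every fold (never reusing full-data
scaling), and metrics are percentages at one decimal.

The published cross-validated 88 % / 91 % / 86 % cannot be reproduced
without the original serum matrix — and those three numbers are in fact
mutually inconsistent with "2 misclassified, both tumor" out of 14 + 11
under any confusion table, so the original bookkeeping is unknowable.
The acceptance stand-in is property-based: on the synthetic design
(14 vs 11, 8 features, |log2fc| ≥ 1, σ = 0.2) the minimum LOO accuracy
over 20 seeds must be ≥ 88 %, and permuted labels must sit at chance
(35–65 %).

## 6. The phantom: a stated world

`default_phantom_spec()` fixes an 8 × 12 mm frame (40 × 60 pixels at
200 µm) with four tissue regions mimicking the imaged anatomy: healthy
ovary and uterus dominated by PI(38:4) at m/z 885.5499 (the ovary with a
cholesterol-sulfate shoulder, the uterus with a PE/PS/PG complement),
a tumor region carrying the full 18-ion annotation panel with chloride
adducts flagged, and a bilirubin-dominated blood-filled cyst sharing two
ceramide chlorides with the tumor. Noise, chosen once as realistic and
not revisited:

* **Pixel gain** — lognormal, σ = 0.25 (multiplicative sensitivity
  variation of ~25 %; spray/surface fluctuation is multiplicative in
  practice).
* **m/z jitter** — Gaussian, σ = 0.003 Th at m/z 850, scaled
  proportionally to m/z (a few ppm of calibration wander).
* **Background** — Poisson(3) peaks per scan, uniform in m/z, exponential
  intensities at 2 % of the region base peak.
* **Chloride isotopes** — every n_chlorine ≥ 1 peak is emitted with an
  M+2 partner at exactly +1.99705 Th and ratio 0.3196 per chlorine.

The phantom emulates spatial contiguity, distinct-but-overlapping
spectral profiles, multiplicative noise and isotope structure. It does
**not** emulate chromatographic/ionization suppression, peak-shape
asymmetry, mass-dependent sensitivity, profile-mode peak width, or
histological texture within a region — so a green phantom test
establishes that the *operators* behave as specified on data with the
stated statistics, not that biological conclusions transfer. The serum
generator likewise emulates only lognormal abundances with fixed fold
changes (6 down / 2 up, the published sign pattern).

The worked axis for phantom-scale tests coarsens the bin width to
0.015 Th at m/z 850 (~5 × 10⁴ channels instead of ~1.6 × 10⁶) purely for
test-budget reasons; the axis code is scale-free and the full-resolution
axis is exercised directly in the binning oracle tests.

## 7. Degenerate inputs and error policy

Rejected with diagnostics: overlapping phantom regions with different
profiles (naming both), scan periods that starve a line of scans, lines
with fewer than two scans (interpolation needs a bracket), empty ROIs,
negative V entries, all-zero spectra, ion windows that miss every channel
(naming the nearest center), [M−H]⁻ on H-free formulas, single-class
fits, and version-mismatched containers (naming both versions). All-zero
V returns the zero factorization with a warning rather than an error, so
batch pipelines can proceed.

## 8. Known limitations

* ALS with clamping has no global convergence guarantee; different seeds
  can reach different local minima (tests therefore fix seeds and assert
  reconstruction-level properties).
* The channel count of the original processed dataset (2,556,741) is not
  reproducible from the published axis parameters; the axis is exposed by
  parameters instead of forcing that count.
* Only singly charged negative adducts ([M−H]⁻, [M+Cl]⁻) and the
  single-chlorine M+2 check are implemented; no isotope fine structure,
  no MS/MS, no lipid nomenclature parsing.
* K-Means feature scaling/initialization of the original analysis is
  unreported; the in-package choices are explicit substitutes.
* The demo's chloride verdicts are computed on the ROI mean spectrum; at
  coarse demo bin widths closely spaced species can share windows.
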