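---
title: "Methods: a serum 1H-NMR chemometrics workflow with a synthetic-cohort generator"
author: "epimetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a serum 1H-NMR chemometrics workflow with a synthetic-cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimetab)
```

## The problem this package addresses

Serum metabolomics by 1D proton NMR is a standard route to class-discovery
questions of the form: do healthy controls (C), drug-responder (R) and
drug-resistant (NR) epilepsy patients carry distinguishable metabolic
profiles? The classical analysis chain is: bin the spectra into fixed-width
chemical-shift buckets, normalize each spectrum to percent total area,
Pareto-scale the bin table, screen for outliers with PCA, fit pairwise
OPLS-DA models, validate them with label permutations and CV-ANOVA, pick
discriminant bins from the S-plot and VIP scores, map those bins to
metabolites, quantify the metabolites against the TSP internal standard, and
confirm group differences with Mann-Whitney tests under a Holm-Bonferroni
correction. In the motivating application the discriminant panel is dominated
by ketone bodies (3-hydroxybutyrate, acetoacetate, acetone, plus acetate),
elevated in drug-resistant patients, against decreased glucose, lactate and
citrate.

`epimetab` implements that chain as tested, reusable functions, and couples
it to a seeded synthetic-spectrum generator so every stage can be exercised
end to end with known ground truth: no clinical spectra are required.

## The synthetic-cohort generator

Spectra are synthesized directly in the frequency domain, already phased, on
a uniform grid of 16,384 points spanning -0.5 to 9.5 ppm (covering the
analyzed 0.6-8.6 ppm window with margin). Each metabolite contributes
first-order multiplets: `multiplicity` Lorentzian lines with binomial
(Pascal-triangle) intensity ratios, spaced `J` Hz apart, with a default
half-width at half-maximum of 1.0 Hz (about 0.002 ppm at the default
499 MHz). A multiplet carrying `n` protons at concentration `c` mM
integrates to `c * n` area units; the same proportionality holds for every
species, including the TSP reference (a 9-proton singlet at 0.0 ppm, fixed
at 0.507 mM, the concentration produced by adding 70 ul of a 5.07 mM stock
to a 700 ul sample: `tsp_final_concentration()`). On top of the signals sit
a polynomial baseline (flat zero by default), a broad residual-water
Lorentzian at 4.79 ppm -- deliberately inside the conventionally excluded
4.64-5.2 ppm window, so default preprocessing removes it -- and white
Gaussian noise with SD expressed as a fraction of the TSP peak height
(default 0.001). Each non-reference multiplet is jittered by a per-sample
normal chemical-shift error (SD 0.003 ppm, small against the 0.04 ppm bin
width); the reference is pinned at 0.0 ppm because it defines the axis.

Per-class concentrations are drawn from normal distributions truncated at
zero (rejection sampling). The bundled library
(`inst/extdata/metabolite_library.yaml`) carries the published class means
and SDs for eight metabolites (3-OH-butyrate, acetate, acetoacetate,
acetone, citrate, glucose, lactate, scyllo-inositol). Four further species
(choline, alanine, glutamate, and the 2-OH-butyrate/2-OH-valerate pair whose
triplets overlap at 0.92 ppm) have no published concentration table; their
distributions are package defaults, ordered C < R < NR with magnitudes in
the 0.05-0.3 mM range, and are tagged `source: default` in the library file
so they are never mistaken for published values. Chemical shifts and J
values are standard serum reference values and are editable in the library
file.

Two consequences of the truncation are worth noting. First, concentrations
are never negative by construction. Second, for a metabolite whose mean is
small against its SD (acetone in controls: 0.0008 +/- 0.001 mM) the
truncated distribution's mean is analytically larger than the nominal one
(mu + sigma * phi(mu/sigma)/Phi(mu/sigma), about 0.00117 mM here). The
generator's tests therefore check empirical means against the truncated law
for every metabolite, and against the nominal class mean only where
mean >= 2 SD, where the truncation shift is negligible. All quantities used
as acceptance anchors (acetone NR, glucose C, lactate C) are in that safe
regime.

What the generator does *not* emulate: broad lipoprotein envelopes and
macromolecular baseline rolls, second-order (strong-coupling) multiplet
distortion, pH- or ion-dependent shift changes beyond random jitter,
relaxation/NOE amplitude corrections, and any FID-level artifact (the
simulation is frequency-domain by design). Passing tests therefore
demonstrate the correctness of the analysis chain and its recovery
properties under a clean, known signal model -- not robustness to every
pathology of real serum spectra.

## Preprocessing: binning and normalization

`build_bin_grid()` lays left-closed right-open bins of exactly 0.04 ppm from
0.6 ppm upward; the last bin is clipped at 8.6 ppm if the range is not a
whole multiple. A bin is dropped when its interval overlaps any exclusion
window at all (whole-bin dropping is the conservative convention; partial
bins would mix excluded signal into retained features). With the
conventional exclusions (4.64-5.2, residual water; 5.28-6.6, noise) this
retains 153 of 200 bins. The analogous published matrix is quoted as 159
bins; no whole-bin convention over the stated range and exclusions yields
159, so the package keeps the grid fully configurable and records the
discrepancy rather than reverse-engineering an undocumented edge rule. The
sample dimension (70) is exactly reproducible and is what the acceptance
checks anchor on.

Bin values are trapezoidal integrals with linear interpolation at bin edges
(the integral of the piecewise-linear interpolant, so bins tile the analysis
range additively to machine precision). Negative noise excursions are
integrated as-is -- clipping would bias areas upward -- and only a
non-positive *total* area makes a sample unusable. Percent normalization
(each row scaled to sum 100) mimics the standard correction for differing
overall serum concentration; note it introduces the usual closure coupling
between bins, which is a property of the method, not a bug of the
implementation.

## Scaling and models

Pareto scaling centres each bin and divides by the square root of its sample
SD (n-1 denominator), the usual NMR compromise that tames intense sugar and
lactate bins without blowing up noise bins the way unit-variance scaling
would. Zero-variance bins are centred only (divisor 1) and flagged. In every
cross-validation split the scaling model is refit on the training rows only
and applied frozen to the held-out rows; anything else leaks test
information into the scaler.

PCA is computed by SVD of the scaled matrix (numerically safer than NIPALS
at these sizes) and is used as a report-only Hotelling T2 outlier screen
with the usual `A(N^2-1)/(N(N-A)) F(A, N-A)` limit.

OPLS-DA codes the two classes 0/1, centres the dummy, and alternates:
weight `w ∝ X'y`, score `t = Xw`, loading `p`, orthogonal weight
`w_o ∝ p - (w'p)w`, orthogonal score/loading, and deflation of X by the
orthogonal component -- then extracts a single predictive component from the
filtered X. The default component spec is one predictive plus one orthogonal
component ("1P + 1O"). `R2Y` is the fitted fraction of y variance; `Q2` is
cross-validated (`1 - PRESS/SS`) with deterministic interleaved 7-fold
assignment (index mod 7 after ordering by class), so CV involves no
randomness and results are exactly reproducible; the fold scheme argument
keeps this pluggable. With zero orthogonal components the fit reduces
exactly (to 1e-10) to one-component NIPALS PLS1, which the tests assert.

## Validation

The permutation diagnostic shuffles the labels, refits, and records the
absolute Pearson correlation `r` between permuted and original centred
labels together with the refit R2Y and Q2. Least-squares lines of R2Y and Q2
against `r` -- over all permuted records plus the unpermuted anchor at
`r = 1` -- give the reported intercepts at `r = 0`. Following the usual
software convention the refits are PLS-DA models with the same total
component count; OPLS refits are available behind an argument. Duplicate
permutations are allowed (the permutation space is astronomically larger
than 500). A heuristic pass/fail (R2 intercept < 0.4, Q2 intercept < 0.05)
is reported but never enforced.

CV-ANOVA compares cross-validated predictive variation against predictive
residuals: `F = ((SS - PRESS)/A) / (PRESS/(N-1-A))`, upper-tail F p-value,
with `PRESS > SS` reported as p = 1. A property worth knowing: under a true
null the model overfits inside every fold, PRESS typically exceeds SS, and
the test returns p = 1 almost always -- so its type-I error rate sits far
*below* the nominal level (simulations in the test suite measure about 1%
at alpha = 0.05). CV-ANOVA is a conservative guard against overfitting, not
a calibrated test; the permutation p-value is the calibrated one.

## Biomarker selection and quantification

The S-plot pairs each bin's covariance `p1 = t'x_j/(N-1)` and correlation
`pcorr1` with the predictive score, computed on the same Pareto-scaled
matrix used for fitting. VIP uses the combined-component formulation
(orthogonal components contribute zero explained y-variance but appear in
the normalization); mean squared VIP is 1 by construction, which the tests
assert on every fitted model. Selection defaults |pcorr1| >= 0.5 and
VIP >= 1 are conventional, not published values. Selected bins are annotated
with every library metabolite owning a multiplet line within 0.02 ppm of the
bin interval; multi-metabolite bins (the 0.92 ppm pair) are flagged
ambiguous, unmatched bins are reported unassigned.

Quantification replaces proprietary spectral-library deconvolution with
targeted integration of one designated, well-isolated multiplet per
metabolite (the designation lives in the library file). The window spans the
multiplet's outer lines plus a per-metabolite margin; a local linear
baseline (the chord between window endpoints, each estimated as a 5-point
neighbourhood mean for noise robustness) is subtracted; and concentration
follows the per-proton ratio against the reference:
`conc = (A_m/n_m) / (A_ref/9) * 0.507 mM`. Because margins differ between
metabolites (acetone at 2.23 ppm needs a tight 0.02 ppm margin to stay clear
of acetoacetate at 2.27 ppm, while lactate can afford 0.05 ppm), raw windows
would truncate different fractions of the Lorentzian area and bias the
ratio by several percent. Each window area is therefore divided by its
analytic captured fraction -- the arctan integral of a unit-area Lorentzian
multiplet over the window, minus the expected chord-baseline bias, computed
from the library lineshape. This keeps differently sized windows mutually
consistent; the correction is exact for isolated multiplets and leaves only
neighbour-tail interference (about 1-2% in the worst cases) as residual
bias. The overlapping 2-OH-butyrate/2-OH-valerate triplets carry no
designated window and return NA with a warning; choline is quantified but
flagged for glucose-envelope proximity. Negative corrected areas are clipped
to zero with a warning; a non-positive reference area is an error.

The univariate screen runs two-sided Mann-Whitney U tests (exact by full
enumeration for n1 + n2 <= 12 without ties, otherwise the tie- and
continuity-corrected normal approximation) with Holm-Bonferroni adjustment,
the family being the metabolites tested within one group-pair comparison.

## Numerical choices and degenerate inputs

* Axis validation: spectra must be strictly ascending and uniform within
  1e-9 relative spacing tolerance; descending files are auto-reversed with a
  flag; duplicated axis values are rejected.
* Interval arithmetic uses a 1e-9 ppm epsilon so exclusion edges that
  coincide with bin edges (as the conventional settings do) never drop a
  touching-but-not-overlapping bin to floating-point noise.
* Zero-variance bins: centred, divisor 1, pcorr1 = 0, flagged everywhere
  they surface.
* The orthogonal iteration stops early (with a warning) if no y-orthogonal
  variation remains; the component spec string records the count actually
  fitted.
* Empirical permutation p-values use the (1 + #{>=})/(n_perm + 1)
  correction, so they are never zero.
* All cohort-level randomness flows through a single recorded seed; the
  caller's RNG state is saved and restored around every seeded operation.

## Problem sizes used by the test and acceptance suites

The suites are sized to run comfortably on a single CPU: cohorts of
35/18/17 (the study design) or 35/0/17 for pairwise recovery; 100 spectra
per group for quantification recovery, with a low-noise acquisition
(noise SD 2e-4 of the TSP peak height) for those runs, since they measure
quantification fidelity rather than noise robustness; 500-1000 repetitions
for type-I-error simulations; 50 seeds for planted-signal recovery; and 100
permutations per seed for null-intercept checks (500 permutations remain the
analysis default in `analysis/03_models.R`).

## Known limitations

* The generator's clean signal model (above) means recovery results bound
  what the pipeline can do on ideal data; real serum spectra add alignment,
  baseline and overlap pathologies that the non-goals exclude.
* Multi-class discrimination is handled pairwise (plus a PCA overview), not
  by a bespoke multi-class OPLS.
* Exact SIMCA-style numbers from proprietary software (CV partitioning,
  component auto-selection) are not bit-reproducible; the package's
  deterministic interleaved CV is documented and stable instead.
* CV-ANOVA conservatism, and the 153-vs-159 bin-count discrepancy, are
  discussed above.
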