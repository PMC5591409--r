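# epimetab

A serum ¹H-NMR metabolomics workflow for three-class drug-response
profiling in epilepsy — healthy controls (C), drug-responder (R) and
drug-resistant / non-responder (NR) patients — built around a seeded
synthetic-spectrum generator with known ground truth, so the entire
analysis chain is testable end to end without any clinical data.

## Who this is for

Analysts building or auditing NMR chemometrics pipelines of the classic
form: spectral binning → percent total-area normalization → Pareto scaling
→ PCA outlier screen → pairwise OPLS-DA → permutation / CV-ANOVA validation
→ S-plot + VIP discriminant selection → internal-standard quantification →
Mann–Whitney + Holm–Bonferroni confirmation. Every stage is a documented,
unit-tested R function; an `analysis/` directory chains them into a
reproducible study-scale workflow.

## The model at the core

For two classes with centred 0/1 dummy $y$ and Pareto-scaled bin matrix
$X$, OPLS-DA splits $X$ into y-predictive and y-orthogonal variation.
With $w \propto X^\top y$, $t = Xw$, $p = X^\top t/(t^\top t)$, the
orthogonal component is $w_o \propto p - (w^\top p)\,w$,
$t_o = X w_o$, $p_o = X^\top t_o/(t_o^\top t_o)$, and $X$ is deflated by
$t_o p_o^\top$ before a single predictive component is extracted
("1P + 1O"). Goodness of fit is $R^2Y = 1 - \|y - tc\|^2/\|y\|^2$;
goodness of prediction is the cross-validated
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ (deterministic interleaved 7-fold
CV, rescaled within each training split). Models are validated by label
permutation ($R^2$/$Q^2$ regressed on the label correlation $r$, with
intercepts at $r = 0$) and by CV-ANOVA,
$F = \frac{(\mathrm{SS}-\mathrm{PRESS})/A}{\mathrm{PRESS}/(N-1-A)}$.
Metabolite concentrations come from targeted multiplet integration against
the TSP internal standard (0.507 mM, 9 protons):
$c_m = \frac{A_m/n_m}{A_\mathrm{ref}/9}\times 0.507\ \mathrm{mM}$,
with chord-baseline subtraction and an analytic Lorentzian capture
correction per window.

The synthetic generator renders frequency-domain spectra as Lorentzian
first-order multiplets (area ∝ concentration × protons), plus baseline,
a residual-water hump inside the excluded region, shift jitter and white
noise; per-class concentrations are drawn from zero-truncated normal
distributions taken from the published class table (eight metabolites) or
flagged package defaults (the rest). See `vignettes/serum-nmr-workflow.Rmd`
for the full methods account.

## Worked example

```r
library(epimetab)

cohort <- simulate_cohort(cohort_design(35, 18, 17, seed = 101))
bm <- bin_cohort(cohort$spectra, build_bin_grid())
bm
#> Bin matrix: 70 samples x 153 bins (groups: C=35, NR=17, R=18)

keep <- bm$group %in% c("C", "NR")
sc  <- pareto_scale(bm$x[keep, ])
fit <- fit_oplsda(sc$x, bm$group[keep], n_orth = 1)
cv  <- cross_validate_q2(bm$x[keep, ], bm$group[keep], n_orth = 1, folds = 7)
fit$Q2 <- cv$q2
fit
#> OPLS-DA C vs NR | components 1P + 1O | R2X 0.500  R2Y 0.958  Q2 0.930
cv_anova(cv)
#> CV-ANOVA: F(2, 49) = 325.448, p = 5.087e-29
permutation_test(bm$x[keep, ], bm$group[keep], n_orth = 1,
                 n_perm = 100, seed = 7)
#> Permutation test (100 permutations, PLS refits): R2 intercept 0.172, Q2 intercept -0.369
#>   empirical P(R2_perm >= R2_model) = 0.009901, P(Q2_perm >= Q2_model) = 0.009901
#>   heuristic: R2 intercept < 0.4 ok; Q2 intercept < 0.05 ok

sel <- select_discriminants(compute_s_plot(fit, sc$x), compute_vip(fit))
map_bins_to_metabolites(sel, bm$grid, build_default_library())[1:3, c("bin_center", "metabolites", "ambiguous")]
#>   bin_center                 metabolites ambiguous
#> 1       0.90 2-OH-butyrate,2-OH-valerate      TRUE
#> 2       0.94 2-OH-butyrate,2-OH-valerate      TRUE
#> 3       1.34                     lactate     FALSE

quantify_against_tsp(cohort$spectra[[1]], "lactate", build_default_library())
#> [1] 1.898  # ground truth for this sample: 1.905 mM
```

Reading: the simulated C-vs-NR contrast is strongly predictive
(Q² = 0.93 against a fitted R²Y = 0.96), survives validation (CV-ANOVA
p ≈ 5e-29; negative Q² permutation intercept; empirical permutation
p = 1/101), and the selected bins point at the planted discriminants —
lactate, the overlapping 2-hydroxy acids at 0.92 ppm (flagged ambiguous),
and the ketone-body region. Quantification recovers the generator's
ground-truth concentration within a few tenths of a percent.

## The analysis workflow

Numbered drivers under `analysis/` re-run the study-scale analysis and
write their tables under `results/analysis/`:

1. `01_simulate.R` — 70-subject cohort (35/18/17), spectra + manifest +
   ground truth
2. `02_bin.R` — 153-bin matrix, percent-normalized
3. `03_models.R` — three pairwise OPLS-DA models with CV, CV-ANOVA and
   500-permutation diagnostics (`model_summary.tsv`)
4. `04_biomarkers.R` — S-plot/VIP discriminants with annotations,
   TSP-referenced concentrations, Mann–Whitney + Holm screen
5. `05_report.R` — consolidated markdown report from the serialized
   intermediates

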