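#!/usr/bin/env Rscript
# Stage 4: biomarker selection, quantification and univariate confirmation.
#
# For each pairwise comparison: S-plot (covariance/correlation with the
# predictive score) + VIP selection of discriminant bins, annotation of the
# selected bins against the metabolite library; then TSP-referenced
# quantification of every designated metabolite across all spectra and the
# Mann-Whitney + Holm-Bonferroni screen per group pair.

library(epimetab)

bm <- read_bin_matrix("results/analysis/bin_matrix.tsv")
spectra <- read_manifest("results/analysis/cohort/manifest.tsv")
lib <- build_default_library()
out <- "results/analysis"

comparisons <- list(c("C", "NR"), c("C", "R"), c("R", "NR"))
for (cmp in comparisons) {
  keep <- bm$group %in% cmp
  sc <- pareto_scale(bm$x[keep, , drop = FALSE])
  fit <- fit_oplsda(sc$x, bm$group[keep], n_orth = 1)
  sp <- compute_s_plot(fit, sc$x)
  vip <- compute_vip(fit)
  sel <- select_discriminants(sp, vip, pcorr_min = 0.5, vip_min = 1.0)
  tag <- paste(cmp, collapse = "_vs_")
  tab <- sp; tab$vip <- vip
  write.table(tab, file.path(out, paste0("splot_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s: %d discriminant bins\n", paste(cmp, collapse = " vs "),
              nrow(sel$selected)))
  if (nrow(sel$selected)) {
    mp <- map_bins_to_metabolites(sel, bm$grid, lib)
    ann <- cbind(sel$selected[c("variable", "p1", "pcorr1", "vip",
                                "higher_in")],
                 mp[c("metabolites", "ambiguous")])
    write.table(ann, file.path(out, paste0("discriminants_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    print(ann[order(-abs(ann$p1)), c("variable", "higher_in", "metabolites")],
          row.names = FALSE)
  }
}

quant <- quantify_cohort(spectra, lib)
write.table(quant, file.path(out, "concentrations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
uni <- univariate_screen(quant, comparisons)
write.table(uni, file.path(out, "univariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nUnivariate screen (Holm-adjusted p < 0.05):\n")
sig <- uni[uni$p_holm < 0.05, c("comparison", "metabolite", "mean_1",
                                "mean_2", "p_raw", "p_holm")]
print(sig, row.names = FALSE, digits = 3)
cat("\nWrote splot/discriminants/concentrations/univariate tables under",
    out, "\n")
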