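#!/usr/bin/env Rscript
# Stage 3: multivariate modelling and validation.
#
# PCA outlier screen on the Pareto-scaled matrix, then one OPLS-DA model
# (1 predictive + 1 orthogonal component) per pairwise class comparison,
# each with 7-fold cross-validated Q2, CV-ANOVA significance, and a
# 500-permutation diagnostic with R2/Q2 intercepts.

library(epimetab)

bm <- read_bin_matrix("results/analysis/bin_matrix.tsv")
out <- "results/analysis"

sc_all <- pareto_scale(bm)
screen <- score_outliers(fit_pca(sc_all$x, 5), alpha = 0.05)
cat(sprintf("PCA outlier screen: %d of %d samples exceed the T2 limit\n\n",
            sum(screen$outlier), nrow(screen)))

comparisons <- list(c("C", "NR"), c("C", "R"), c("R", "NR"))
summary_rows <- list()
for (i in seq_along(comparisons)) {
  cmp <- comparisons[[i]]
  keep <- bm$group %in% cmp
  x <- bm$x[keep, , drop = FALSE]
  y <- bm$group[keep]
  sc <- pareto_scale(x)
  fit <- fit_oplsda(sc$x, y, n_orth = 1)
  cv <- cross_validate_q2(x, y, n_orth = 1, folds = 7)
  fit$Q2 <- cv$q2
  an <- cv_anova(cv)
  pt <- permutation_test(x, y, n_orth = 1, n_perm = 500, seed = 100 + i)
  tag <- paste(cmp, collapse = "_vs_")
  scores <- data.frame(sample_id = bm$sample_id[keep], group = y,
                       t_pred = fit$t, t_orth1 = fit$T_o[, 1])
  write.table(scores, file.path(out, paste0("scores_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pt$records, file.path(out, paste0("permutation_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_rows[[i]] <- data.frame(
    comparison = paste(cmp, collapse = " vs "), components = fit$components,
    R2Xcum = round(fit$R2X, 3), R2Ycum = round(fit$R2Y, 3),
    Q2cum = round(cv$q2, 3), p_cvanova = signif(an$p, 3),
    R2_intercept = round(pt$r2_intercept, 3),
    Q2_intercept = round(pt$q2_intercept, 3))
}
model_summary <- do.call(rbind, summary_rows)
write.table(model_summary, file.path(out, "model_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Per-comparison model summary (components, fit, prediction, validation):\n")
print(model_summary, row.names = FALSE)
cat("\nAll three pairwise models should show Q2 well above 0, CV-ANOVA\n")
cat("p << 0.05 and negative Q2 permutation intercepts: the synthetic class\n")
cat("separation is strong and survives validation.\n")
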