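#!/usr/bin/env Rscript
# Stage 5: consolidated report.
#
# Pure function of the serialized stage outputs: collects the model summary,
# discriminant tables and univariate screen into a single markdown report.

out <- "results/analysis"
ms <- read.delim(file.path(out, "model_summary.tsv"), check.names = FALSE)
uni <- read.delim(file.path(out, "univariate.tsv"))

md <- c("# Serum NMR metabolomics workflow report", "",
        "## Pairwise OPLS-DA models", "",
        paste(capture.output(print(ms, row.names = FALSE)), collapse = "\n"),
        "", "## Discriminant bins per comparison", "")
for (f in list.files(out, pattern = "^discriminants_.*\\.tsv$")) {
  tab <- read.delim(file.path(out, f))
  cmp <- gsub("_", " ", sub("^discriminants_(.*)\\.tsv$", "\\1", f))
  md <- c(md, paste0("### ", cmp), "",
          paste0("- bin ", tab$variable, " ppm -> ", tab$metabolites,
                 " (higher in ", tab$higher_in, ")",
                 ifelse(tab$ambiguous, " [ambiguous]", "")), "")
}
sig <- uni[uni$p_holm < 0.05, ]
md <- c(md, "## Metabolites significant after Holm correction", "",
        if (nrow(sig)) paste0("- ", sig$comparison, ": ", sig$metabolite,
                              " (Holm p = ", signif(sig$p_holm, 2), ")")
        else "- none", "")
writeLines(md, file.path(out, "report.md"))
cat("Wrote", file.path(out, "report.md"), "\n")
cat(paste(md, collapse = "\n"), "\n")
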