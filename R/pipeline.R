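# End-to-end orchestration: simulate or ingest spectra, bin, fit pairwise
# OPLS-DA models with validation, select and quantify discriminant
# metabolites, and emit a reproducible report.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the conventional
#' defaults: 0.04-ppm bins over 0.6-8.6 ppm with the water/noise exclusions,
#' 1 predictive + 1 orthogonal component, 7-fold cross-validation, 500
#' permutations, alpha = 0.05, and the three pairwise comparisons
#' C vs NR, C vs R, R vs NR.
#'
#' @param mode `"simulate"` (generate a cohort from `design`) or `"manifest"`
#'   (read spectra listed in `manifest`)
#' @param design a [cohort_design()] (simulate mode)
#' @param manifest path to a cohort manifest (manifest mode)
#' @param library a [metabolite_library()] or path to a library file
#' @param acq an [acquisition_params()] (simulate mode)
#' @param grid a [build_bin_grid()]
#' @param comparisons list of 2-vectors of group labels
#' @param n_orth,folds,n_perm,alpha model/validation settings
#' @param pcorr_min,vip_min discriminant-selection thresholds
#' @param perm_seed seed for the permutation shuffles
#' @param out_dir optional directory for serialized outputs
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("simulate", "manifest"),
                            design = cohort_design(),
                            manifest = NULL,
                            library = build_default_library(),
                            acq = acquisition_params(),
                            grid = build_bin_grid(),
                            comparisons = list(c("C", "NR"), c("C", "R"),
                                               c("R", "NR")),
                            n_orth = 1, folds = 7, n_perm = 500,
                            alpha = 0.05,
                            pcorr_min = 0.5, vip_min = 1.0,
                            perm_seed = 1,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(library)) library <- read_metabolite_library(library)
  if (mode == "manifest") {
    if (is.null(manifest) || !file.exists(manifest))
      stop("manifest mode requires an existing manifest file")
  }
  declared <- c("C", "R", "NR")
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% declared))
      stop("invalid comparison '", paste(cmp, collapse = ":"),
           "': groups must be two of ", paste(declared, collapse = ", "))
  }
  structure(list(mode = mode, design = design, manifest = manifest,
                 library = library, acq = acq, grid = grid,
                 comparisons = comparisons, n_orth = n_orth, folds = folds,
                 n_perm = n_perm, alpha = alpha, pcorr_min = pcorr_min,
                 vip_min = vip_min, perm_seed = perm_seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# cheap deterministic checksum of the configuration for provenance
.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), c("library"))]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain spectra (simulate or read), bin + normalize +
#' assemble, PCA outlier screen (report-only), then per configured
#' comparison: Pareto scaling, OPLS-DA fit, cross-validated Q2, CV-ANOVA,
#' permutation diagnostics, S-plot/VIP discriminant selection and bin
#' annotation; finally TSP-referenced quantification of the designated
#' metabolites and the Mann-Whitney/Holm univariate screen. Deterministic
#' given the same configuration and seeds.
#'
#' @param config a [pipeline_config()]
#' @return an object of class `run_report` (see [generate_report()] for the
#'   serialized form)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spectra <- if (config$mode == "simulate") {
    simulate_cohort(config$design, config$library, config$acq)$spectra
  } else {
    read_manifest(config$manifest)
  }
  groups <- vapply(spectra, `[[`, character(1), "group")
  for (cmp in config$comparisons)
    if (!all(cmp %in% groups))
      stop("comparison ", paste(cmp, collapse = " vs "),
           " references a group absent from the data")

  bm <- bin_cohort(spectra, config$grid)
  sc_all <- pareto_scale(bm)
  pca <- fit_pca(sc_all$x, n_comp = min(5L, nrow(bm$x) - 1L, ncol(bm$x)))
  outliers <- score_outliers(pca, config$alpha)

  comparison_results <- lapply(seq_along(config$comparisons), function(i) {
    cmp <- config$comparisons[[i]]
    keep <- bm$group %in% cmp
    x_sub <- bm$x[keep, , drop = FALSE]
    y <- bm$group[keep]
    sc <- pareto_scale(x_sub)
    fit <- fit_oplsda(sc$x, y, n_orth = config$n_orth)
    cv <- cross_validate_q2(x_sub, y, n_orth = config$n_orth,
                            folds = config$folds)
    fit$Q2 <- cv$q2
    anova <- cv_anova(cv)
    perm <- permutation_test(x_sub, y, n_orth = config$n_orth,
                             n_perm = config$n_perm,
                             seed = config$perm_seed + i,
                             folds = config$folds)
    splot <- compute_s_plot(fit, sc$x)
    vip <- compute_vip(fit)
    discs <- select_discriminants(splot, vip, config$pcorr_min,
                                  config$vip_min)
    mapping <- if (nrow(discs$selected))
      map_bins_to_metabolites(discs, config$grid, config$library) else NULL
    scores <- data.frame(sample_id = bm$sample_id[keep], group = y,
                         t_pred = fit$t)
    if (ncol(fit$T_o))
      scores <- cbind(scores, stats::setNames(
        as.data.frame(fit$T_o), paste0("t_orth", seq_len(ncol(fit$T_o)))))
    list(comparison = paste(cmp, collapse = " vs "), fit = fit, cv = cv,
         anova = anova, perm = perm, splot = splot, vip = vip,
         discriminants = discs, mapping = mapping, scores = scores)
  })

  quant <- quantify_cohort(spectra, config$library,
                           frequency = config$acq$frequency)
  univariate <- univariate_screen(quant, config$comparisons)

  model_summary <- do.call(rbind, lapply(comparison_results, function(res)
    data.frame(comparison = res$comparison,
               components = res$fit$components,
               R2Xcum = res$fit$R2X, R2Ycum = res$fit$R2Y,
               Q2cum = res$cv$q2, p_cvanova = res$anova$p,
               R2_intercept = res$perm$r2_intercept,
               Q2_intercept = res$perm$q2_intercept)))

  report <- structure(list(model_summary = model_summary,
                           comparisons = comparison_results,
                           pca = pca, outliers = outliers,
                           bin_matrix = bm, quant = quant,
                           univariate = univariate,
                           config = config,
                           provenance = list(
                             config_hash = .config_hash(config),
                             seeds = c(cohort = if (config$mode == "simulate")
                               config$design$seed else NA_integer_,
                               permutation = config$perm_seed),
                             package_version =
                               as.character(utils::packageVersion("epimetab")))),
                      class = "run_report")
  if (!is.null(config$out_dir)) generate_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", nrow(x$bin_matrix$x), "samples x",
      ncol(x$bin_matrix$x), "bins;",
      sum(x$outliers$outlier), "T2 outlier(s) flagged\n")
  print(x$model_summary, row.names = FALSE)
  invisible(x)
}

#' Serialize a run report to tab-separated and markdown files
#'
#' Emits, under `out_dir`: `model_summary.tsv` (the per-comparison component
#' table: components, R2Xcum, R2Ycum, Q2cum, CV-ANOVA p, permutation
#' intercepts), per-comparison `scores_*.tsv`, `permutation_*.tsv`,
#' `splot_*.tsv`, `discriminants_*.tsv`, plus `concentrations.tsv`,
#' `univariate.tsv`, `bin_matrix.tsv`, `provenance.txt` and a human-readable
#' `report.md`. Pure function of the report: regenerating from the same
#' report reproduces identical files.
#'
#' @param report a `run_report` from [run_pipeline()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
generate_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$model_summary, "model_summary.tsv")
  wt(report$quant, "concentrations.tsv")
  wt(report$univariate, "univariate.tsv")
  wt(report$outliers, "pca_outliers.tsv")
  write_bin_matrix(report$bin_matrix, file.path(out_dir, "bin_matrix.tsv"))
  slug <- function(s) gsub("[^A-Za-z0-9]+", "_", s)
  for (res in report$comparisons) {
    tag <- slug(res$comparison)
    wt(res$scores, paste0("scores_", tag, ".tsv"))
    wt(res$perm$records, paste0("permutation_", tag, ".tsv"))
    sp <- res$splot; sp$vip <- res$vip
    wt(sp, paste0("splot_", tag, ".tsv"))
    if (!is.null(res$mapping)) {
      dd <- res$discriminants$selected
      dd$metabolites <- res$mapping$metabolites
      dd$ambiguous <- res$mapping$ambiguous
      wt(dd, paste0("discriminants_", tag, ".tsv"))
    }
  }
  md <- c("# NMR metabolomics pipeline report", "",
          "## Model summary", "",
          paste(utils::capture.output(print(report$model_summary,
                                            row.names = FALSE)),
                collapse = "\n"),
          "", "## Outlier screen",
          sprintf("%d of %d samples exceed the Hotelling T2 limit.",
                  sum(report$outliers$outlier), nrow(report$outliers)),
          "", "## Discriminant metabolites", "")
  for (res in report$comparisons) {
    md <- c(md, paste0("### ", res$comparison), "")
    if (is.null(res$mapping)) {
      md <- c(md, "No variable passed the selection thresholds.", "")
    } else {
      md <- c(md, paste0("- bin ", res$mapping$bin_center, " ppm: ",
                         res$mapping$metabolites,
                         ifelse(res$mapping$ambiguous, " (ambiguous)", "")),
              "")
    }
  }
  writeLines(md, file.path(out_dir, "report.md"))
  writeLines(c(paste0("config_hash: ", report$provenance$config_hash),
               paste0("cohort_seed: ", report$provenance$seeds["cohort"]),
               paste0("permutation_seed: ",
                      report$provenance$seeds["permutation"]),
               paste0("package_version: ",
                      report$provenance$package_version)),
             file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}
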