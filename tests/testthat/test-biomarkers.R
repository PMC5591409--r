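test_that("S-plot columns equal direct covariance and correlation with the score", {
  # hand-computable 4-sample, 2-variable fixture
  x <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  x <- sweep(x, 2, colMeans(x))
  y <- c("A", "A", "B", "B")
  fit <- fit_oplsda(x, y, n_orth = 0)
  sp <- compute_s_plot(fit, x)
  expect_equal(sp$p1, apply(x, 2, function(col) cov(fit$t, col)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sp$pcorr1, apply(x, 2, function(col) cor(fit$t, col)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-12))
  expect_true(all(sign(sp$p1) == sign(sp$pcorr1) |
                    sp$p1 == 0 | sp$pcorr1 == 0))

  # a variable proportional to the score has pcorr1 = 1
  x2 <- cbind(fit$t * 2, x)
  fit2 <- fit_oplsda(x2, y, n_orth = 0)
  sp2 <- compute_s_plot(fit2, x2)
  expect_equal(abs(sp2$pcorr1[1]), 1, tolerance = 1e-9)

  # independent noise decorrelates as 1/sqrt(N)
  set.seed(71)
  n <- 1000
  yb <- rep(c("A", "B"), each = n / 2)
  xb <- cbind(as.numeric(yb == "B") + 0.1 * rnorm(n), rnorm(n))
  xb <- sweep(xb, 2, colMeans(xb))
  fitb <- fit_oplsda(xb, yb, n_orth = 0)
  expect_lt(abs(compute_s_plot(fitb, xb)$pcorr1[2]), 0.1)

  # zero-variance variables flagged with pcorr1 = 0
  x3 <- cbind(x, 0)
  fit3 <- fit_oplsda(x3, y, n_orth = 0)
  sp3 <- compute_s_plot(fit3, x3)
  expect_true(sp3$zero_variance[3])
  expect_equal(sp3$pcorr1[3], 0)
})

test_that("VIP scores are normalized and rank informative variables first", {
  pm <- planted_matrix(n = 30, p = 7, effect = 3, seed = 72)
  sc <- pareto_scale(pm$x)
  for (n_orth in 0:2) {
    fit <- fit_oplsda(sc$x, pm$y, n_orth = n_orth)
    vip <- compute_vip(fit)
    expect_equal(sum(vip^2), length(vip), tolerance = 1e-8)
    expect_true(all(vip >= 0))
  }
  fit <- fit_oplsda(sc$x, pm$y, n_orth = 1)
  # only column 1 carries class signal
  expect_gt(compute_vip(fit)[1], 1)
  expect_equal(unname(which.max(compute_vip(fit))), 1L)

  # single-variable model: normalization forces VIP = 1
  y <- rep(c("A", "B"), each = 4)
  x1 <- matrix(as.numeric(y == "B") - 0.5 + 0.01 * rnorm(8), 8, 1)
  expect_equal(unname(compute_vip(fit_oplsda(x1, y, 0))), 1,
               tolerance = 1e-9)

  # two-variable model, signal only in variable 1: VIP1 > 1 > VIP2
  set.seed(73)
  x2 <- cbind(as.numeric(y == "B") + 0.05 * rnorm(8), rnorm(8))
  x2 <- sweep(x2, 2, colMeans(x2))
  v2 <- compute_vip(fit_oplsda(x2, y, 0))
  expect_gt(v2[1], 1)
  expect_lt(v2[2], 1)
})

test_that("discriminant selection applies both thresholds and keeps direction", {
  pm <- planted_matrix(n = 30, p = 6, effect = 3, seed = 74)
  sc <- pareto_scale(pm$x)
  fit <- fit_oplsda(sc$x, pm$y, n_orth = 0)
  sp <- compute_s_plot(fit, sc$x)
  vip <- compute_vip(fit)

  all_sel <- select_discriminants(sp, vip, 0, 0)
  expect_equal(nrow(all_sel$selected), 6)
  none <- select_discriminants(sp, vip, 1.01, Inf)
  expect_equal(nrow(none$selected), 0)

  sel <- select_discriminants(sp, vip, 0.5, 1.0)
  expect_true(all(abs(sel$selected$pcorr1) >= 0.5))
  expect_true(all(sel$selected$vip >= 1.0))
  # column 1 is elevated in class B by construction
  idx <- which(sel$selected$variable == 1)
  expect_length(idx, 1)
  expect_equal(sel$selected$higher_in[idx], "B")
})

test_that("bins annotate to metabolites with ambiguity and unassigned reporting", {
  lib <- build_default_library()
  grid <- build_bin_grid()
  mp <- map_bins_to_metabolites(c(1.34, 0.94, 8.42), grid, lib)
  expect_equal(mp$metabolites[1], "lactate")
  expect_false(mp$ambiguous[1])
  expect_equal(mp$metabolites[2], "2-OH-butyrate,2-OH-valerate")
  expect_true(mp$ambiguous[2])
  expect_equal(mp$n_matches[2], 2)
  expect_equal(mp$metabolites[3], "unassigned")
})

test_that("TSP-referenced quantification is a per-proton area ratio", {
  # identity: equal per-proton area => the reference concentration
  probe_lib <- function(conc_margin = 0.05) metabolite_library(
    list(metabolite_spec("probe", list(multiplet(3.0, 1, 0, 2)),
                         list(C = list(mean = 1, sd = 0, source = "default")),
                         quant = list(multiplet = 1, margin = conc_margin))),
    tsp_reference_spec())
  lib <- probe_lib()
  s <- render_spectrum(c(probe = 0.507), lib, clean_acq())
  expect_equal(quantify_against_tsp(s, "probe", lib), 0.507,
               tolerance = 0.002)
  # doubling the per-proton area doubles the estimate
  s2 <- render_spectrum(c(probe = 1.014), lib, clean_acq())
  expect_equal(quantify_against_tsp(s2, "probe", lib), 1.014,
               tolerance = 0.002)

  # round-trip closure at the published control lactate level
  tl <- tiny_library()
  s3 <- render_spectrum(c(lactate = 1.88, acetone = 0), tl, clean_acq())
  expect_equal(quantify_against_tsp(s3, "lactate", tl), 1.88,
               tolerance = 0.02 * 1.88)

  # metabolites without a designated window return NA with a warning
  full <- build_default_library()
  s4 <- render_spectrum(
    setNames(rep(0.1, length(full$metabolites)),
             vapply(full$metabolites, `[[`, character(1), "name")),
    full, clean_acq())
  expect_warning(v <- quantify_against_tsp(s4, "2-OH-butyrate", full),
                 "overlap")
  expect_true(is.na(v))
})

test_that("Mann-Whitney p-values match full enumeration on tie-free samples", {
  # canonical small case: complete separation of 2 vs 2
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-4)
  expect_true(mw$exact)

  # exhaustive comparison against the enumeration oracle, n1 + n2 <= 10
  set.seed(81)
  for (rep in 1:30) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    vals <- sample(seq(0.5, 50, by = 0.5), n1 + n2)  # tie-free
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$p, oracle_mw_exact_p(a, b), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
    # U definition: min of the two one-sided counts, bounded by n1*n2
    expect_gte(mw$U, 0)
    expect_lte(mw$U, n1 * n2)
  }

  # identical multisets: no separation
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")

  # large tied samples fall back to the corrected normal approximation
  set.seed(82)
  big <- mann_whitney_u(round(rnorm(35), 1), round(rnorm(17), 1))
  expect_false(big$exact)
  expect_true(big$p >= 0 && big$p <= 1)
})

test_that("Holm adjustment equals the step-down oracle and dominates raw p", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.5, 0.9)), c(1, 1))

  set.seed(83)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_bonferroni(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # Holm never exceeds plain Bonferroni
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
    # monotone in raw-p rank order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  # tied raw p receive equal adjusted values
  expect_equal(holm_bonferroni(c(0.02, 0.02, 0.5))[1],
               holm_bonferroni(c(0.02, 0.02, 0.5))[2])
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the univariate screen mirrors the per-comparison table layout", {
  set.seed(84)
  co <- simulate_cohort(cohort_design(8, 0, 8, seed = 85), tiny_library(),
                        acquisition_params(noise_sd = 2e-4))
  quant <- quantify_cohort(co$spectra, tiny_library())
  uni <- univariate_screen(quant, comparisons = list(c("C", "NR")))
  expect_setequal(uni$metabolite, c("lactate", "acetone"))
  expect_true(all(uni$p_holm >= uni$p_raw - 1e-12))
  # the simulated lactate effect (1.88 vs 1.16, tight SDs) is detected
  expect_lt(uni$p_holm[uni$metabolite == "lactate"], 0.01)
  expect_equal(uni$comparison, rep("C vs NR", 2))
})
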