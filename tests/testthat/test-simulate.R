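test_that("concentration sampling follows the truncated per-class law", {
  lib <- build_default_library()

  # degenerate SDs: assignment equals the group means exactly
  lib0 <- lib
  for (i in seq_along(lib0$metabolites))
    for (g in names(lib0$metabolites[[i]]$distributions))
      lib0$metabolites[[i]]$distributions[[g]]$sd <- 0
  a <- sample_concentrations(lib0, "C")
  expect_equal(unname(a["glucose"]), 2.02)
  expect_equal(unname(a["lactate"]), 1.88)

  # determinism for a fixed RNG state
  set.seed(99); a1 <- sample_concentrations(lib, "NR")
  set.seed(99); a2 <- sample_concentrations(lib, "NR")
  expect_identical(a1, a2)

  expect_error(sample_concentrations(lib, "Z"), "unknown group")

  # truncation never yields negative concentrations
  set.seed(5)
  draws <- replicate(300, sample_concentrations(lib, "C"))
  expect_true(all(draws >= 0))

  # NR lactate: sample mean within 3 SE of the published class mean
  set.seed(6)
  lac <- replicate(1e4, {
    repeat { x <- rnorm(1, 1.16, 0.05); if (x >= 0) break }
    x
  })
  expect_lt(abs(mean(lac) - 1.16), 3 * 0.05 / sqrt(1e4))
})

test_that("empirical group means match the generator law at n = 500 per group", {
  lib <- build_default_library()
  set.seed(7)
  for (g in c("C", "R", "NR")) {
    draws <- replicate(500, sample_concentrations(lib, g))
    for (i in seq_along(lib$metabolites)) {
      d <- lib$metabolites[[i]]$distributions[[g]]
      se <- d$sd / sqrt(500)
      # the generator's actual law is the zero-truncated normal
      mu_trunc <- epimetab:::.truncnorm_mean(d$mean, d$sd)
      expect_lt(abs(mean(draws[i, ]) - mu_trunc), 4 * se + 1e-12,
                label = paste(g, lib$metabolites[[i]]$name))
      # where truncation is negligible the nominal mean is recovered too
      if (d$mean >= 2 * d$sd)
        expect_lt(abs(mean(draws[i, ]) - d$mean), 4 * se,
                  label = paste(g, lib$metabolites[[i]]$name, "(nominal)"))
    }
  }
})

test_that("rendered spectra are linear in concentration with Lorentzian areas", {
  lib <- tiny_library()
  acq <- clean_acq()

  # all concentrations zero: only the TSP singlet remains
  s0 <- render_spectrum(c(lactate = 0, acetone = 0), lib, acq)
  expect_equal(oracle_trapz(s0$ppm, s0$intensity), 0.507 * 9,
               tolerance = 1e-2)
  far <- abs(s0$ppm) > 0.5
  expect_lt(max(abs(s0$intensity[far])), 1e-2 * max(s0$intensity))

  # doubling a concentration doubles the multiplet-window integral
  s1 <- render_spectrum(c(lactate = 1, acetone = 0), lib, acq)
  s2 <- render_spectrum(c(lactate = 2, acetone = 0), lib, acq)
  win <- s1$ppm > 1.1 & s1$ppm < 1.6
  a1 <- oracle_trapz(s1$ppm[win], (s1$intensity - s0$intensity)[win])
  a2 <- oracle_trapz(s2$ppm[win], (s2$intensity - s0$intensity)[win])
  expect_equal(a2 / a1, 2, tolerance = 1e-9)

  # area ratio lactate/TSP equals (conc * protons) / (0.507 * 9)
  s <- render_spectrum(c(lactate = 1.5, acetone = 0), lib, acq)
  wl <- s$ppm > 1.03 & s$ppm < 1.63
  wr <- abs(s$ppm) < 0.3
  ratio <- oracle_trapz(s$ppm[wl], s$intensity[wl]) /
    oracle_trapz(s$ppm[wr], s$intensity[wr])
  expect_equal(ratio, (1.5 * 3) / (0.507 * 9), tolerance = 0.01)

  # noiseless multiplet area matches the analytic Lorentzian integral < 1%
  m <- lib$metabolites[[1]]$multiplets[[1]]
  lines <- multiplet_lines(m, acq$frequency)
  g <- m$linewidth / acq$frequency
  analytic <- sum(lines$ratio * (atan((1.63 - lines$position) / g) -
                                   atan((1.03 - lines$position) / g)) / pi) *
    1.5 * 3
  expect_equal(oracle_trapz(s$ppm[wl], s$intensity[wl]), analytic,
               tolerance = 0.01)

  expect_error(
    render_spectrum(c(lactate = 1, acetone = 0), lib,
                    acquisition_params(ppm_min = 1, ppm_max = 9)),
    "cover")
  expect_error(render_spectrum(c(lactate = 1), lib, acq), "cover|metabolites")
})

test_that("cohort simulation is reproducible and carries matching ground truth", {
  lib <- tiny_library()
  acq <- acquisition_params(n_points = 4096)
  d <- cohort_design(3, 0, 2, seed = 42)
  co1 <- simulate_cohort(d, lib, acq)
  co2 <- simulate_cohort(d, lib, acq)

  expect_length(co1$spectra, 5)
  expect_equal(vapply(co1$spectra, `[[`, character(1), "group"),
               c("C", "C", "C", "NR", "NR"))
  expect_false(anyDuplicated(vapply(co1$spectra, `[[`, character(1),
                                    "sample_id")) > 0)
  # truth rows: one per sample x metabolite, all non-negative
  expect_equal(nrow(co1$truth), 5 * 2)
  expect_true(all(co1$truth$conc_mM >= 0))

  # same seed => byte-identical truth and spectra
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$spectra[[4]]$intensity, co2$spectra[[4]]$intensity)

  # degenerate composition: SD 0, noise 0 => truth equals the class means
  lib0 <- lib
  for (i in seq_along(lib0$metabolites))
    for (g in names(lib0$metabolites[[i]]$distributions))
      lib0$metabolites[[i]]$distributions[[g]]$sd <- 0
  co0 <- simulate_cohort(cohort_design(1, 0, 0, seed = 1), lib0, clean_acq())
  expect_equal(co0$truth$conc_mM,
               c(1.88, 0.0008))

  expect_error(cohort_design(0, 0, 0), "zero")
})

test_that("simulation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_design(1, 0, 1, seed = 9),
                            tiny_library(),
                            acquisition_params(n_points = 4096)))
  expect_identical(.Random.seed, before)
})
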