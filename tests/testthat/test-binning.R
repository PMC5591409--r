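test_that("bin grids follow the whole-bin exclusion convention", {
  # no exclusions over the conventional range: 200 bins of 0.04 ppm
  g0 <- build_bin_grid(0.6, 8.6, 0.04, exclusions = list())
  expect_equal(nrow(g0$bins), 200)
  expect_equal(g0$bins$left[1], 0.6)
  expect_equal(g0$bins$right[200], 8.6, tolerance = 1e-9)

  g2 <- build_bin_grid(0, 1, 0.5, exclusions = list())
  expect_equal(nrow(g2$bins), 2)
  expect_equal(g2$bins$left, c(0, 0.5))
  expect_equal(g2$bins$right, c(0.5, 1))

  # conventional serum grid: water + noise exclusions retain 153 bins,
  # matching the interval-enumeration oracle
  g <- build_bin_grid()
  expect_equal(nrow(g$bins), 153)
  expect_equal(nrow(g$bins),
               oracle_bin_count(0.6, 8.6, 0.04,
                                list(c(4.64, 5.2), c(5.28, 6.6))))
  # no retained bin overlaps an excluded region
  for (iv in g$exclusions)
    expect_false(any(g$bins$left < iv[2] - 1e-9 &
                       g$bins$right > iv[1] + 1e-9))

  # width >= range collapses to a single (clipped) bin
  g1 <- build_bin_grid(0, 1, 5, exclusions = list())
  expect_equal(nrow(g1$bins), 1)
  expect_equal(unlist(g1$bins), c(left = 0, right = 1))

  # overlapping exclusions are merged, not an error
  gm <- build_bin_grid(0, 1, 0.1,
                       exclusions = list(c(0.2, 0.5), c(0.4, 0.7)))
  expect_length(gm$exclusions, 1)
  expect_equal(gm$exclusions[[1]], c(0.2, 0.7))
})

test_that("retained-bin counts match the enumeration oracle on random grids", {
  set.seed(31)
  for (i in 1:40) {
    lo <- runif(1, 0, 2)
    hi <- lo + runif(1, 0.5, 8)
    width <- runif(1, 0.02, 0.6)
    n_ex <- sample(0:3, 1)
    excl <- replicate(n_ex, {
      a <- runif(1, lo, hi); b <- min(hi, a + runif(1, 0.05, 1)); c(a, b)
    }, simplify = FALSE)
    g <- build_bin_grid(lo, hi, width, exclusions = excl)
    expect_equal(nrow(g$bins), oracle_bin_count(lo, hi, width, excl),
                 info = sprintf("lo=%g hi=%g w=%g", lo, hi, width))
  }
})

test_that("bin integration is trapezoidal with edge interpolation", {
  g <- build_bin_grid(0.6, 8.6, 0.04, exclusions = list())
  ppm <- seq(-0.5, 9.5, length.out = 8192)

  # constant intensity: every bin integrates to width * level
  s1 <- nmr_spectrum(ppm, rep(1, length(ppm)))
  b1 <- bin_spectrum(s1, g)
  expect_equal(b1$values, rep(0.04, 200), tolerance = 1e-9)

  s0 <- nmr_spectrum(ppm, rep(0, length(ppm)))
  expect_equal(bin_spectrum(s0, g)$values, rep(0, 200))

  # single Lorentzian inside one bin: matches fine-grid quadrature and the
  # analytic arctan area within 1%
  gamma <- 0.002
  lor <- function(x) (1 / pi) * gamma / ((x - 2.22)^2 + gamma^2)
  s2 <- nmr_spectrum(ppm, lor(ppm))
  b2 <- bin_spectrum(s2, g)
  k <- which(g$bins$left <= 2.22 & g$bins$right > 2.22)
  fine <- seq(g$bins$left[k], g$bins$right[k], length.out = 40001)
  expect_equal(b2$values[k], oracle_trapz(fine, lor(fine)), tolerance = 0.01)
  expect_equal(b2$values[k],
               (atan((g$bins$right[k] - 2.22) / gamma) -
                  atan((g$bins$left[k] - 2.22) / gamma)) / pi,
               tolerance = 0.01)
  expect_lt(sum(b2$values[-k][abs(bin_centers(g)[-k] - 2.22) > 0.1]), 0.05)

  # partition additivity: bins tile the full analysis range
  set.seed(32)
  s3 <- nmr_spectrum(ppm, rnorm(length(ppm)))
  b3 <- bin_spectrum(s3, g)
  total <- epimetab:::.integrate_interval(s3$ppm, s3$intensity, 0.6, 8.6)
  expect_equal(sum(b3$values), total, tolerance = 1e-9)

  # coverage precondition
  short <- nmr_spectrum(seq(1, 9, length.out = 512), rep(1, 512))
  expect_error(bin_spectrum(short, g), "cover")
})

test_that("percent normalization rescales rows to 100 and rejects empty samples", {
  g <- build_bin_grid(0, 3, 1, exclusions = list())
  mk <- function(v, id = "s") structure(
    list(sample_id = id, group = "C", values = v, normalized = FALSE,
         grid = g),
    class = "binned_sample")
  expect_equal(normalize_percent(mk(c(1, 1, 2)))$values, c(25, 25, 50))
  g1 <- build_bin_grid(0, 1, 1, exclusions = list())
  one <- structure(list(sample_id = "s", group = "C", values = 5,
                        normalized = FALSE, grid = g1),
                   class = "binned_sample")
  expect_equal(normalize_percent(one)$values, 100)
  expect_error(normalize_percent(mk(c(0, 0, 0))), "non-positive total area")
})

test_that("bin-matrix assembly preserves order, enforces grids, and round-trips", {
  lib <- tiny_library()
  acq <- acquisition_params(n_points = 8192, noise_sd = 1e-4)
  co <- simulate_cohort(cohort_design(2, 0, 2, seed = 8), lib, acq)
  g <- build_bin_grid()
  binned <- lapply(co$spectra, function(s)
    normalize_percent(bin_spectrum(s, g)))
  bm <- assemble_bin_matrix(binned, g)
  expect_equal(dim(bm$x), c(4, 153))
  expect_equal(bm$sample_id, vapply(co$spectra, `[[`, character(1),
                                    "sample_id"))
  expect_equal(unname(rowSums(bm$x)), rep(100, 4), tolerance = 1e-6)

  expect_error(assemble_bin_matrix(list(), g), "no samples")
  expect_error(assemble_bin_matrix(binned[c(1, 1)], g), "duplicate")
  expect_error(assemble_bin_matrix(lapply(co$spectra, function(s)
    bin_spectrum(s, g)), g), "not normalized")
  g2 <- build_bin_grid(0.6, 8.6, 0.08)
  mixed <- c(binned[1], list(normalize_percent(
    bin_spectrum(co$spectra[[2]], g2))))
  expect_error(assemble_bin_matrix(mixed, g), "mixed")

  one <- assemble_bin_matrix(binned[1], g)
  expect_equal(nrow(one$x), 1)
  expect_equal(unname(rowSums(one$x)), 100, tolerance = 1e-6)

  # serialized matrix re-reads at 12 significant digits
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_bin_matrix(bm, path)
  bm2 <- read_bin_matrix(path)
  expect_equal(bm2$group, bm$group)
  expect_equal(unname(bm2$x), unname(bm$x), tolerance = 1e-10)
  expect_equal(nrow(bm2$grid$bins), 153)
})

test_that("small shift jitter barely moves isolated singlet bins", {
  # singlet at a bin centre; jitter well under the bin width
  lib <- metabolite_library(
    list(metabolite_spec("probe", list(multiplet(2.22, 1, 0, 3)),
                         list(C = list(mean = 1, sd = 0, source = "default")),
                         quant = list(multiplet = 1, margin = 0.05))),
    tsp_reference_spec())
  g <- build_bin_grid()
  k <- which(g$bins$left <= 2.22 & g$bins$right > 2.22)
  base <- bin_spectrum(render_spectrum(c(probe = 1), lib, clean_acq()), g)
  set.seed(33)
  for (i in 1:5) {
    jit <- bin_spectrum(render_spectrum(
      c(probe = 1), lib,
      acquisition_params(noise_sd = 0, water_area = 0,
                         shift_jitter_sd = 0.003)), g)
    expect_lt(abs(jit$values[k] - base$values[k]) / base$values[k], 0.05)
  }
})
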