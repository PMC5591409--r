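#' Acquisition parameters for the frequency-domain spectrum generator
#'
#' Spectra are synthesized directly in the frequency domain on a uniform ppm
#' grid, already phased: Lorentzian multiplet lines on top of a polynomial
#' baseline, a broad residual-water hump inside the conventionally excluded
#' region, and white Gaussian noise. Intensity units are arbitrary but
#' consistent: every species (including the reference) contributes a total
#' integrated area of `concentration x protons` area units.
#'
#' @param frequency spectrometer frequency in MHz
#' @param ppm_min,ppm_max extent of the output grid (must cover -0.1..8.6 ppm)
#' @param n_points number of grid points
#' @param noise_sd Gaussian noise SD as a fraction of the reference (TSP) peak
#'   height
#' @param baseline polynomial baseline coefficients (ascending powers of ppm),
#'   in intensity units
#' @param shift_jitter_sd per-sample, per-multiplet chemical-shift jitter SD
#'   (ppm); the reference is pinned at its nominal shift (it defines the axis)
#' @param water_center,water_area,water_hwhm residual-water hump: a broad
#'   Lorentzian (centre ppm, area in the same units as metabolite signals,
#'   half-width at half-maximum in ppm)
#' @return an object of class `acquisition_params`
#' @export
acquisition_params <- function(frequency = 499,
                               ppm_min = -0.5, ppm_max = 9.5,
                               n_points = 16384,
                               noise_sd = 0.001,
                               baseline = 0,
                               shift_jitter_sd = 0.003,
                               water_center = 4.79,
                               water_area = 3,
                               water_hwhm = 0.1) {
  stopifnot(frequency > 0, ppm_max > ppm_min, n_points >= 16,
            noise_sd >= 0, shift_jitter_sd >= 0,
            water_area >= 0, water_hwhm > 0)
  structure(list(frequency = frequency, ppm_min = ppm_min, ppm_max = ppm_max,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 baseline = baseline, shift_jitter_sd = shift_jitter_sd,
                 water_center = water_center, water_area = water_area,
                 water_hwhm = water_hwhm),
            class = "acquisition_params")
}

#' Cohort design for the synthetic-spectrum generator
#'
#' Default group sizes are the study's printed cohort: 35 healthy controls,
#' 18 drug-responder and 17 drug-resistant (non-responder) patients.
#'
#' @param n_c,n_r,n_nr group sizes (controls / responders / non-responders)
#' @param seed integer random seed recorded with the output
#' @return an object of class `cohort_design`
#' @export
cohort_design <- function(n_c = 35, n_r = 18, n_nr = 17, seed = 1) {
  stopifnot(n_c >= 0, n_r >= 0, n_nr >= 0)
  if (n_c + n_r + n_nr == 0) stop("all group sizes are zero")
  structure(list(n_c = as.integer(n_c), n_r = as.integer(n_r),
                 n_nr = as.integer(n_nr), seed = as.integer(seed)),
            class = "cohort_design")
}

#' Draw per-metabolite concentrations for one sample
#'
#' Each concentration is drawn from the metabolite's group-specific normal
#' distribution truncated at zero (rejection sampling: redraw until >= 0).
#' Uses the current RNG state; callers control reproducibility with a seed.
#'
#' @param library a [metabolite_library()]
#' @param group group label, one of `"C"`, `"R"`, `"NR"`
#' @return named numeric vector of concentrations (mM)
#' @export
sample_concentrations <- function(library, group) {
  if (!group %in% c("C", "R", "NR"))
    stop("unknown group label '", group, "'")
  out <- vapply(library$metabolites, function(m) {
    d <- m$distributions[[group]]
    if (is.null(d)) stop("metabolite '", m$name,
                         "' has no distribution for group '", group, "'")
    if (d$sd == 0) return(d$mean)
    repeat {
      x <- stats::rnorm(1, d$mean, d$sd)
      if (x >= 0) return(x)
    }
  }, numeric(1))
  names(out) <- vapply(library$metabolites, `[[`, character(1), "name")
  out
}

#' Render one frequency-domain spectrum
#'
#' Intensity at each grid point is baseline + residual-water hump + noise +
#' the sum over all multiplet lines of Lorentzian peaks
#' `L(d) = (A/pi) g / ((d - d0')^2 + g^2)` with `g` the linewidth in ppm
#' (HWHM in Hz divided by the spectrometer frequency) and `d0'` the nominal
#' line position plus per-multiplet jitter. Each multiplet's total area is
#' `concentration x protons` area units, the same proportionality for every
#' species including the reference.
#'
#' @param assignment named concentration vector (mM) covering every library
#'   metabolite
#' @param library a [metabolite_library()]
#' @param acq an [acquisition_params()]
#' @param sample_id,group identifiers stored in the returned spectrum
#' @return an object of class `nmr_spectrum` (fields `sample_id`, `group`,
#'   `ppm`, `intensity`)
#' @export
render_spectrum <- function(assignment, library, acq = acquisition_params(),
                            sample_id = "sample", group = NA_character_) {
  ppm <- seq(acq$ppm_min, acq$ppm_max, length.out = acq$n_points)
  if (ppm[1] > -0.1 + 1e-12 || ppm[length(ppm)] < 8.6 - 1e-12)
    stop("acquisition grid must cover [-0.1, 8.6] ppm")
  nms <- vapply(library$metabolites, `[[`, character(1), "name")
  missing <- setdiff(nms, names(assignment))
  if (length(missing))
    stop("assignment does not cover library metabolites: ",
         paste(missing, collapse = ", "))

  intensity <- .eval_poly(acq$baseline, ppm)
  if (acq$water_area > 0)
    intensity <- intensity +
      .lorentz(ppm, acq$water_center, acq$water_hwhm, acq$water_area)

  add_species <- function(intensity, spec, conc, jitter_sd) {
    for (m in spec$multiplets) {
      jit <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
      lines <- multiplet_lines(m, acq$frequency)
      g <- m$linewidth / acq$frequency
      area <- conc * m$protons
      for (k in seq_len(nrow(lines)))
        intensity <- intensity +
          .lorentz(ppm, lines$position[k] + jit, g, area * lines$ratio[k])
    }
    intensity
  }

  ref <- library$reference
  intensity <- add_species(intensity, ref, ref$concentration, 0)
  for (i in seq_along(library$metabolites))
    intensity <- add_species(intensity, library$metabolites[[i]],
                             assignment[[nms[i]]], acq$shift_jitter_sd)

  if (acq$noise_sd > 0) {
    m1 <- ref$multiplets[[1]]
    href <- ref$concentration * m1$protons * max(
      multiplet_lines(m1, acq$frequency)$ratio) /
      (pi * m1$linewidth / acq$frequency)
    intensity <- intensity + stats::rnorm(length(ppm), 0, acq$noise_sd * href)
  }

  structure(list(sample_id = sample_id, group = group,
                 ppm = ppm, intensity = intensity),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("1H-NMR spectrum '%s' (group %s): %d points, %.2f..%.2f ppm\n",
              x$sample_id, x$group, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Simulate a cohort of serum spectra with known ground truth
#'
#' Draws per-sample concentrations from the library's per-class distributions
#' and renders one spectrum per subject. Fully reproducible from the design
#' seed; the caller's RNG state is left untouched.
#'
#' @param design a [cohort_design()]
#' @param library a [metabolite_library()]
#' @param acq an [acquisition_params()]
#' @return an object of class `nmr_cohort`: `spectra` (list of
#'   `nmr_spectrum`), `truth` (data.frame `sample_id`, `group`, `metabolite`,
#'   `conc_mM`), plus the `design`, `library` and `acq` used
#' @export
simulate_cohort <- function(design = cohort_design(),
                            library = build_default_library(),
                            acq = acquisition_params()) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- rep(c("C", "R", "NR"), c(design$n_c, design$n_r, design$n_nr))
  ids <- unlist(lapply(c(C = design$n_c, R = design$n_r, NR = design$n_nr),
                       function(n) seq_len(n)), use.names = FALSE)
  ids <- sprintf("%s%02d", groups, ids)
  nms <- vapply(library$metabolites, `[[`, character(1), "name")

  .with_seed(design$seed, {
    spectra <- vector("list", length(ids))
    truth <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      conc <- sample_concentrations(library, groups[i])
      spectra[[i]] <- render_spectrum(conc, library, acq,
                                      sample_id = ids[i], group = groups[i])
      truth[[i]] <- data.frame(sample_id = ids[i], group = groups[i],
                               metabolite = nms, conc_mM = unname(conc))
    }
    structure(list(spectra = spectra,
                   truth = do.call(rbind, truth),
                   design = design, library = library, acq = acq),
              class = "nmr_cohort")
  })
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic NMR cohort: %d spectra (C=%d, R=%d, NR=%d), seed %d\n",
    length(x$spectra), x$design$n_c, x$design$n_r, x$design$n_nr,
    x$design$seed))
  invisible(x)
}

# analytic mean of a normal(mean, sd) truncated at zero (rejection-sampler law)
.truncnorm_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}
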