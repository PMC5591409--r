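# Discriminant-variable selection (S-plot covariance/correlation + VIP),
# bin-to-metabolite annotation, TSP-referenced targeted quantification, and
# the univariate confirmation (Mann-Whitney U + Holm-Bonferroni).

#' S-plot table for a fitted OPLS-DA model
#'
#' Per variable j: `p1_j = cov(t, x_j) = t'x_j/(N-1)` and
#' `pcorr1_j = p1_j / (sd(t) sd(x_j))`, computed on the same scaled matrix
#' the model was fitted on. Zero-variance variables get `pcorr1 = 0` and are
#' flagged.
#'
#' @param model a fitted [fit_oplsda()] model
#' @param x the scaled matrix the model was fitted on
#' @return data.frame `variable`, `p1`, `pcorr1`, `zero_variance`; the class
#'   positively associated with the predictive score is stored in the
#'   `positive_class` attribute
#' @export
compute_s_plot <- function(model, x) {
  x <- unclass(x)
  stopifnot(inherits(model, "oplsda"), is.matrix(x),
            nrow(x) == length(model$t), ncol(x) == length(model$w))
  N <- nrow(x)
  t_ <- model$t
  p1 <- drop(crossprod(x, t_ - mean(t_))) / (N - 1)
  sdx <- apply(x, 2, stats::sd)
  zero <- sdx <= .Machine$double.eps
  pcorr1 <- ifelse(zero, 0, p1 / (stats::sd(t_) * ifelse(zero, 1, sdx)))
  out <- data.frame(variable = colnames(x) %||% seq_len(ncol(x)),
                    p1 = p1, pcorr1 = pcorr1, zero_variance = zero)
  attr(out, "positive_class") <-
    if (model$c >= 0) model$levels[2] else model$levels[1]
  attr(out, "levels") <- model$levels
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variable importance in projection (VIP)
#'
#' Standard PLS VIP over all components a (predictive + orthogonal):
#' `VIP_j = sqrt(J * sum_a(w_aj^2 SSY_a) / sum_a SSY_a)` with `SSY_a` the
#' y-variance explained by component a. Orthogonal components explain no
#' y-variance (SSY = 0) but participate in the weight normalization; with
#' each weight vector unit-norm the mean squared VIP is 1 by construction.
#'
#' @param model a fitted [fit_oplsda()] model
#' @param variant `"combined"` (all components) or `"predictive"`
#'   (predictive weights only); with a single predictive component the two
#'   coincide
#' @return named numeric vector of VIP scores (one per variable)
#' @export
compute_vip <- function(model, variant = c("combined", "predictive")) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "oplsda"))
  W <- if (variant == "combined") cbind(model$w, model$W_o)
       else cbind(model$w)
  ssy <- c(model$R2Y * model$ssy, rep(0, ncol(W) - 1))
  J <- nrow(W)
  vip <- sqrt(J * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- names(model$w)
  vip
}

#' Select discriminant variables from S-plot and VIP tables
#'
#' A variable is selected iff `|pcorr1| >= pcorr_min` and `VIP >= vip_min`;
#' the direction of change follows the sign of the covariance and the class
#' coding. An empty selection is allowed and reported.
#'
#' @param splot a [compute_s_plot()] table
#' @param vip a [compute_vip()] vector aligned with `splot`
#' @param pcorr_min,vip_min selection thresholds
#' @return an object of class `discriminant_set`: the selected subset with a
#'   `higher_in` column, plus the thresholds used
#' @export
select_discriminants <- function(splot, vip, pcorr_min = 0.5, vip_min = 1.0) {
  stopifnot(nrow(splot) == length(vip))
  pos <- attr(splot, "positive_class")
  lev <- attr(splot, "levels")
  sel <- abs(splot$pcorr1) >= pcorr_min & vip >= vip_min
  tab <- splot[sel, , drop = FALSE]
  tab$vip <- vip[sel]
  tab$higher_in <- ifelse(tab$p1 >= 0, pos, setdiff(lev, pos))
  structure(list(selected = tab,
                 thresholds = c(pcorr_min = pcorr_min, vip_min = vip_min),
                 n_candidates = nrow(splot)),
            class = "discriminant_set")
}

#' @export
print.discriminant_set <- function(x, ...) {
  if (!nrow(x$selected)) {
    cat("Discriminant set: EMPTY (no variable passed |pcorr1| >=",
        x$thresholds["pcorr_min"], "and VIP >=", x$thresholds["vip_min"], ")\n")
  } else {
    cat(sprintf("Discriminant set: %d of %d variables (|pcorr1| >= %.2f, VIP >= %.2f)\n",
                nrow(x$selected), x$n_candidates,
                x$thresholds["pcorr_min"], x$thresholds["vip_min"]))
  }
  invisible(x)
}

#' Annotate discriminant bins with candidate metabolites
#'
#' Each selected bin is annotated with every library metabolite having a
#' multiplet line within `tolerance` ppm of the bin interval. Bins matching
#' two or more metabolites are flagged ambiguous (e.g. the 0.92 ppm bin maps
#' to both overlapping 2-OH acids); bins matching none are reported
#' unassigned.
#'
#' @param discs a [select_discriminants()] result whose variables are bin
#'   centres, or a numeric vector of bin centres
#' @param grid the [build_bin_grid()] the bins came from
#' @param library a [metabolite_library()]
#' @param tolerance ppm tolerance around the bin interval
#' @return data.frame `bin_center`, `left`, `right`, `metabolites`
#'   (comma-separated, `"unassigned"` if none), `n_matches`, `ambiguous`
#' @export
map_bins_to_metabolites <- function(discs, grid, library, tolerance = 0.02) {
  centers <- if (inherits(discs, "discriminant_set"))
    as.numeric(as.character(discs$selected$variable)) else as.numeric(discs)
  idx <- vapply(centers, function(ct) {
    i <- which.min(abs(bin_centers(grid) - ct))
    if (abs(bin_centers(grid)[i] - ct) > grid$width) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx)) stop("bin centre not found on the grid")
  rows <- lapply(seq_along(idx), function(k) {
    l <- grid$bins$left[idx[k]]; r <- grid$bins$right[idx[k]]
    hits <- vapply(library$metabolites, function(m) {
      pos <- unlist(lapply(m$multiplets, function(mm)
        multiplet_lines(mm)$position))
      any(pos >= l - tolerance & pos < r + tolerance)
    }, logical(1))
    nm <- vapply(library$metabolites, `[[`, character(1), "name")[hits]
    data.frame(bin_center = centers[k], left = l, right = r,
               metabolites = if (length(nm)) paste(nm, collapse = ",")
                             else "unassigned",
               n_matches = length(nm), ambiguous = length(nm) >= 2L)
  })
  do.call(rbind, rows)
}

# expected captured fraction of a unit-area Lorentzian multiplet over
# [a, b] after chord-baseline subtraction (truncation minus chord bias)
.window_capture <- function(m, a, b, frequency) {
  lines <- multiplet_lines(m, frequency)
  g <- m$linewidth / frequency
  cap <- sum(lines$ratio * (atan((b - lines$position) / g) -
                              atan((a - lines$position) / g)) / pi)
  hgt <- function(x) sum(lines$ratio * (g / pi) /
                           ((x - lines$position)^2 + g^2))
  cap - (b - a) * (hgt(a) + hgt(b)) / 2
}

# chord-baseline-corrected trapezoidal area over [a, b]; window endpoints are
# estimated as the mean intensity over `edge_points` grid points around each
# edge to keep the chord robust to point noise
.window_area <- function(s, a, b, edge_points = 5L) {
  raw <- .integrate_interval(s$ppm, s$intensity, a, b)
  edge_mean <- function(x0) {
    i <- which.min(abs(s$ppm - x0))
    k <- max(1L, i - edge_points %/% 2L):min(length(s$ppm),
                                             i + edge_points %/% 2L)
    mean(s$intensity[k])
  }
  raw - (b - a) * (edge_mean(a) + edge_mean(b)) / 2
}

#' Quantify a metabolite against the internal TSP reference
#'
#' Integrates the metabolite's designated multiplet window and the reference
#' window (both chord-baseline-corrected trapezoidal areas) and converts to
#' concentration by per-proton ratio:
#' `conc = (A_m / n_m) / (A_ref / n_ref) * conc_ref`. By default each window
#' area is first divided by the analytic captured fraction of a unit-area
#' Lorentzian multiplet over that window (truncation and chord bias computed
#' from the library lineshape), so windows of different widths remain
#' mutually consistent. Metabolites without a designated window (fully
#' overlapped signals) return `NA` with a warning; negative areas are clipped
#' to zero with a warning.
#'
#' @param s an `nmr_spectrum` covering both windows
#' @param metabolite a [metabolite_spec()] with a `quant` designation, or a
#'   metabolite name to look up in `library`
#' @param library a [metabolite_library()] providing the reference (and the
#'   lookup for `metabolite` given as a name)
#' @param frequency spectrometer frequency in MHz (line-position conversion)
#' @param capture_correction divide window areas by their analytic captured
#'   fraction (default `TRUE`)
#' @return concentration in mM (scalar; `NA` if the metabolite has no
#'   designated window)
#' @export
quantify_against_tsp <- function(s, metabolite, library,
                                 frequency = 499,
                                 capture_correction = TRUE) {
  stopifnot(inherits(s, "nmr_spectrum"))
  m <- if (is.character(metabolite)) lib_metabolite(library, metabolite)
       else metabolite
  stopifnot(inherits(m, "metabolite_spec"))
  if (is.null(m$quant)) {
    warning("metabolite '", m$name,
            "' has no designated quantification window (overlapped signal); ",
            "returning NA")
    return(NA_real_)
  }
  if (isTRUE(m$quant$overlap))
    warning("quantification window of '", m$name,
            "' overlaps a neighbouring signal")
  ref <- library$reference
  win <- function(spec, q) {
    mm <- spec$multiplets[[q$multiplet]]
    pos <- multiplet_lines(mm, frequency)$position
    c(min(pos) - q$margin, max(pos) + q$margin, mm$protons)
  }
  wm <- win(m, m$quant)
  wr <- win(ref, ref$quant)
  a_m <- .window_area(s, wm[1], wm[2])
  a_ref <- .window_area(s, wr[1], wr[2])
  if (capture_correction) {
    a_m <- a_m / .window_capture(m$multiplets[[m$quant$multiplet]],
                                 wm[1], wm[2], frequency)
    a_ref <- a_ref / .window_capture(ref$multiplets[[ref$quant$multiplet]],
                                     wr[1], wr[2], frequency)
  }
  if (a_ref <= 0) stop("non-positive reference area")
  if (a_m < 0) {
    warning("negative area for '", m$name, "' clipped to 0")
    a_m <- 0
  }
  (a_m / wm[3]) / (a_ref / wr[3]) * ref$concentration
}

#' Quantify every designated metabolite across a set of spectra
#'
#' @param spectra list of `nmr_spectrum` objects
#' @param library a [metabolite_library()]
#' @param metabolites metabolite names to quantify (default: all with a
#'   designated window)
#' @param frequency spectrometer frequency in MHz
#' @return long data.frame `sample_id`, `group`, `metabolite`, `conc_mM`
#' @export
quantify_cohort <- function(spectra, library, metabolites = NULL,
                            frequency = 499) {
  nms <- vapply(library$metabolites, `[[`, character(1), "name")
  quantifiable <- nms[!vapply(library$metabolites,
                              function(m) is.null(m$quant), logical(1))]
  if (is.null(metabolites)) metabolites <- quantifiable
  rows <- lapply(spectra, function(s) {
    conc <- vapply(metabolites, function(nm)
      suppressWarnings(quantify_against_tsp(s, nm, library, frequency)),
      numeric(1))
    data.frame(sample_id = s$sample_id, group = s$group,
               metabolite = metabolites, conc_mM = unname(conc))
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U = min(U_a, U_b)` with midrank tie handling. The p-value is exact (full
#' enumeration of the U distribution) when `n_a + n_b <= 12` and the data are
#' tie-free, otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b numeric value vectors (each non-empty)
#' @return list with `U`, two-sided `p`, `n1`, `n2`, and whether the exact
#'   distribution was used
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u_a, n1 * n2 - u_a)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n1 + n2 <= 12) && !ties
  p <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  list(U = u, p = min(p, 1), n1 = n1, n2 = n2, exact = exact)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p vector of raw p-values in `[0, 1]`
#' @return adjusted p-values in the input order
#' @export
holm_bonferroni <- function(p) {
  .stopifnot_prob(p)
  stats::p.adjust(p, method = "holm")
}

#' Univariate confirmation screen over quantified concentrations
#'
#' For each group pair, runs a two-sided Mann-Whitney U test per metabolite
#' and applies the Holm-Bonferroni correction within that comparison's family
#' of metabolites. Metabolites with missing concentrations (not quantified)
#' are dropped from the family.
#'
#' @param quant long concentration table from [quantify_cohort()]
#' @param comparisons list of 2-vectors of group labels
#' @return data.frame `comparison`, `metabolite`, group means and SDs, `U`,
#'   `p_raw`, `p_holm`
#' @export
univariate_screen <- function(quant,
                              comparisons = list(c("C", "R"), c("C", "NR"),
                                                 c("R", "NR"))) {
  stopifnot(all(c("group", "metabolite", "conc_mM") %in% names(quant)))
  out <- lapply(comparisons, function(cmp) {
    sub <- quant[quant$group %in% cmp & !is.na(quant$conc_mM), ]
    mets <- unique(sub$metabolite)
    rows <- lapply(mets, function(nm) {
      va <- sub$conc_mM[sub$metabolite == nm & sub$group == cmp[1]]
      vb <- sub$conc_mM[sub$metabolite == nm & sub$group == cmp[2]]
      if (!length(va) || !length(vb)) return(NULL)
      mw <- mann_whitney_u(va, vb)
      data.frame(comparison = paste(cmp, collapse = " vs "),
                 metabolite = nm,
                 mean_1 = mean(va), sd_1 = stats::sd(va),
                 mean_2 = mean(vb), sd_2 = stats::sd(vb),
                 U = mw$U, p_raw = mw$p)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) tab$p_holm <- holm_bonferroni(tab$p_raw)
    tab
  })
  do.call(rbind, out)
}
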