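#' First-order NMR multiplet definition
#'
#' A multiplet is rendered as `multiplicity` Lorentzian lines spaced `J` Hz
#' apart with binomial (Pascal-triangle) intensity ratios, centred at `center`
#' ppm, carrying `protons` equivalent 1H and a Lorentzian half-width at
#' half-maximum of `linewidth` Hz.
#'
#' @param center chemical shift of the multiplet centre (ppm)
#' @param multiplicity number of lines (1 = singlet, 2 = doublet, ...)
#' @param J line spacing in Hz (ignored for singlets)
#' @param protons number of contributing protons (>= 1)
#' @param linewidth Lorentzian half-width at half-maximum in Hz (> 0)
#' @return an object of class `multiplet`
#' @export
multiplet <- function(center, multiplicity = 1L, J = 7, protons, linewidth = 1.0) {
  multiplicity <- as.integer(multiplicity)
  stopifnot(is.numeric(center), length(center) == 1L,
            multiplicity >= 1L, protons >= 1, linewidth > 0, J >= 0)
  structure(list(center = center, multiplicity = multiplicity, J = J,
                 protons = protons, linewidth = linewidth),
            class = "multiplet")
}

#' Line positions and intensity ratios of a multiplet
#'
#' @param m a [multiplet()]
#' @param frequency spectrometer frequency in MHz (converts J from Hz to ppm)
#' @return data.frame with columns `position` (ppm) and `ratio` (sums to 1)
#' @export
multiplet_lines <- function(m, frequency = 499) {
  k <- m$multiplicity
  offs <- (seq_len(k) - (k + 1) / 2) * m$J / frequency
  ratio <- choose(k - 1, seq_len(k) - 1) / 2^(k - 1)
  data.frame(position = m$center + offs, ratio = ratio)
}

#' Metabolite specification
#'
#' Bundles the multiplets of one metabolite with its per-class concentration
#' distributions (normal, truncated at zero) and the designated
#' quantification window.
#'
#' @param name metabolite name (unique within a library)
#' @param multiplets list of [multiplet()] objects
#' @param distributions named list (`C`, `R`, `NR`) of lists with elements
#'   `mean`, `sd` (mM, both >= 0) and `source` (`"paper"` or `"default"`)
#' @param quant `NULL` (metabolite is not quantified, e.g. fully overlapped
#'   signals) or a list with `multiplet` (index of the multiplet to
#'   integrate), `margin` (ppm added on each side of the outer lines) and
#'   `overlap` (flag: a neighbouring species contributes to the window)
#' @return an object of class `metabolite_spec`
#' @export
metabolite_spec <- function(name, multiplets, distributions, quant = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(multiplets) >= 1L)
  for (m in multiplets) stopifnot(inherits(m, "multiplet"))
  total_protons <- sum(vapply(multiplets, `[[`, numeric(1), "protons"))
  stopifnot(total_protons > 0)
  for (g in names(distributions)) {
    d <- distributions[[g]]
    if (!is.numeric(d$mean) || !is.numeric(d$sd) || d$mean < 0 || d$sd < 0)
      stop("metabolite '", name, "', group '", g,
           "': concentration mean and SD must be >= 0")
    if (is.null(d$source)) distributions[[g]]$source <- "default"
  }
  if (!is.null(quant)) {
    stopifnot(quant$multiplet >= 1, quant$multiplet <= length(multiplets),
              quant$margin > 0)
    if (is.null(quant$overlap)) quant$overlap <- FALSE
  }
  structure(list(name = name, multiplets = multiplets,
                 distributions = distributions, quant = quant),
            class = "metabolite_spec")
}

#' Metabolite library
#'
#' @param metabolites list of [metabolite_spec()] objects with unique names
#' @param reference the internal-standard spec; a [metabolite_spec()] with an
#'   extra `concentration` element (fixed mM, > 0)
#' @return an object of class `metabolite_library`
#' @export
metabolite_library <- function(metabolites, reference) {
  nms <- vapply(metabolites, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("metabolite names must be unique")
  stopifnot(inherits(reference, "metabolite_spec"),
            is.numeric(reference$concentration), reference$concentration > 0)
  structure(list(metabolites = metabolites, reference = reference),
            class = "metabolite_library")
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat("Metabolite library:", length(x$metabolites), "metabolites + reference",
      sprintf("%s (%.3f mM)\n", x$reference$name, x$reference$concentration))
  for (m in x$metabolites) {
    src <- unique(vapply(m$distributions, `[[`, character(1), "source"))
    cat(sprintf("  %-16s %d multiplet(s) at %s ppm [%s]\n", m$name,
                length(m$multiplets),
                paste(vapply(m$multiplets, `[[`, numeric(1), "center"),
                      collapse = ", "),
                paste(src, collapse = "/")))
  }
  invisible(x)
}

#' Look up a metabolite by name
#'
#' @param library a [metabolite_library()]
#' @param name metabolite name
#' @return the matching [metabolite_spec()]
#' @export
lib_metabolite <- function(library, name) {
  nms <- vapply(library$metabolites, `[[`, character(1), "name")
  i <- match(name, nms)
  if (is.na(i)) stop("metabolite '", name, "' not in library")
  library$metabolites[[i]]
}

.parse_multiplet <- function(m) {
  multiplet(center = m$center, multiplicity = m$multiplicity,
            J = m$J, protons = m$protons, linewidth = m$linewidth)
}

#' Read a metabolite library from a structured text (YAML) file
#'
#' The file schema is documented in the bundled
#' `extdata/metabolite_library.yaml`: a `reference` entry (internal standard
#' with fixed concentration) and a `metabolites` list, each with multiplets,
#' per-class truncated-normal concentration distributions tagged
#' `source: paper|default`, and an optional designated quantification window.
#'
#' @param path path to the library file
#' @return a [metabolite_library()]
#' @export
read_metabolite_library <- function(path) {
  raw <- yaml::read_yaml(path)
  mets <- lapply(raw$metabolites, function(entry) {
    metabolite_spec(name = entry$name,
                    multiplets = lapply(entry$multiplets, .parse_multiplet),
                    distributions = entry$distributions,
                    quant = entry$quant)
  })
  ref <- metabolite_spec(name = raw$reference$name,
                         multiplets = lapply(raw$reference$multiplets,
                                             .parse_multiplet),
                         distributions = list(),
                         quant = raw$reference$quant)
  ref$concentration <- raw$reference$concentration_mM
  metabolite_library(mets, ref)
}

#' Write a metabolite library to a YAML file
#'
#' @param library a [metabolite_library()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metabolite_library <- function(library, path) {
  unmult <- function(m) list(center = m$center, multiplicity = m$multiplicity,
                             J = m$J, protons = m$protons,
                             linewidth = m$linewidth)
  out <- list(
    reference = list(name = library$reference$name,
                     concentration_mM = library$reference$concentration,
                     multiplets = lapply(library$reference$multiplets, unmult),
                     quant = library$reference$quant),
    metabolites = lapply(library$metabolites, function(m) {
      e <- list(name = m$name, multiplets = lapply(m$multiplets, unmult))
      if (!is.null(m$quant)) e$quant <- m$quant
      e$distributions <- m$distributions
      e
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Default serum metabolite library
#'
#' Loads the bundled library: the eight metabolites with published per-class
#' concentration distributions (3-OH-butyrate, acetate, acetoacetate, acetone,
#' citrate, glucose, lactate, scyllo-inositol), four additional metabolites
#' with `source: default` distributions (choline, alanine, glutamate, and the
#' 2-OH-butyrate / 2-OH-valerate pair sharing overlapping triplets at
#' 0.92 ppm), and the TSP reference (9-proton singlet at 0.0 ppm, fixed at
#' 0.507 mM).
#'
#' @param path optional path to an alternative library file
#' @return a [metabolite_library()]
#' @export
build_default_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolite_library.yaml",
                        package = "epimetab", mustWork = TRUE)
  read_metabolite_library(path)
}

#' Final concentration of an internal standard after reconstitution
#'
#' Simple dilution arithmetic: a stock at `stock_mM` added as `stock_ul`
#' microlitres into a final volume of `total_ul` microlitres. With the default
#' serum protocol (70 ul of 5.07 mM TSP into 630 ul D2O, 700 ul total) this
#' gives the 0.507 mM working reference concentration.
#'
#' @param stock_mM stock concentration (mM)
#' @param stock_ul volume of stock added (ul)
#' @param total_ul final sample volume (ul)
#' @return final concentration in mM
#' @export
tsp_final_concentration <- function(stock_mM = 5.07, stock_ul = 70,
                                    total_ul = 630 + 70) {
  stopifnot(stock_mM >= 0, stock_ul > 0, total_ul >= stock_ul)
  stock_mM * stock_ul / total_ul
}
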