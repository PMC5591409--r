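# Spectrum file dialect: two-column numeric text `ppm<TAB>intensity` with a
# `#`-comment header carrying the sample id and group; a separate manifest
# (`sample_id  group  path`) defines cohorts.

#' Construct a spectrum object
#'
#' @param ppm strictly ascending, uniform chemical-shift axis (ppm)
#' @param intensity intensity values, one per grid point
#' @param sample_id,group identifiers
#' @return an object of class `nmr_spectrum`
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample",
                         group = NA_character_) {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ")
  if (!.is_uniform_ascending(ppm))
    stop("non-uniform axis: ppm grid must be strictly ascending and uniform")
  structure(list(sample_id = sample_id, group = group,
                 ppm = as.numeric(ppm), intensity = as.numeric(intensity)),
            class = "nmr_spectrum")
}

#' Write a spectrum to a two-column text file
#'
#' @param s an `nmr_spectrum`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample_id: ", s$sample_id),
               paste0("# group: ", s$group),
               "# columns: ppm intensity"), con)
  writeLines(sprintf("%.17g\t%.17g", s$ppm, s$intensity), con)
  invisible(path)
}

#' Read a spectrum from a two-column text file
#'
#' Validates a strictly monotone, uniform ppm axis (1e-9 relative tolerance on
#' the spacing). A descending axis is reversed to ascending and flagged via
#' the `reversed` attribute; a duplicated or irregular axis is rejected.
#'
#' @param path path to a file written by [write_spectrum()] (or any
#'   two-column `ppm intensity` text file with optional `#` headers)
#' @return an `nmr_spectrum`
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(body, "[\t ]+")
  if (any(lengths(parts) != 2L))
    stop("malformed spectrum row(s): expected two numeric columns")
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(ppm) || anyNA(intensity))
    stop("malformed spectrum row(s): non-numeric values")
  reversed <- FALSE
  if (length(ppm) >= 2 && all(diff(ppm) < 0)) {
    ppm <- rev(ppm); intensity <- rev(intensity); reversed <- TRUE
    warning("descending ppm axis reversed to ascending")
  }
  if (!.is_uniform_ascending(ppm))
    stop("non-uniform axis: ppm grid must be strictly ascending and uniform")
  s <- structure(list(sample_id = get_field("sample_id"),
                      group = get_field("group"),
                      ppm = ppm, intensity = intensity),
                 class = "nmr_spectrum")
  attr(s, "reversed") <- reversed
  s
}

#' Write a cohort's spectra, manifest and ground truth to a directory
#'
#' @param cohort an `nmr_cohort` from [simulate_cohort()]
#' @param dir output directory (created if missing)
#' @return path to the manifest file, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nmr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$spectra, function(s) {
    fn <- paste0(s$sample_id, ".tsv")
    write_spectrum(s, file.path(dir, fn))
    data.frame(sample_id = s$sample_id, group = s$group, path = fn)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest and its spectra
#'
#' @param path manifest file (`sample_id  group  path`, tab-separated; paths
#'   are resolved relative to the manifest's directory)
#' @return list of `nmr_spectrum` objects
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    s <- read_spectrum(file.path(base, man$path[i]))
    s$sample_id <- man$sample_id[i]
    s$group <- man$group[i]
    s
  })
}
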