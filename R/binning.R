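# Spectral binning: fixed-width buckets over an analysis range with excluded
# windows, trapezoidal in-bin integration, percent total-area normalization,
# and assembly of the samples x bins matrix.

.merge_intervals <- function(intervals) {
  if (!length(intervals)) return(list())
  m <- do.call(rbind, lapply(intervals, function(iv) {
    stopifnot(length(iv) == 2L, iv[1] < iv[2])
    iv
  }))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    else out[[length(out) + 1L]] <- m[i, ]
  }
  out
}

#' Build a bin grid with exclusion windows
#'
#' Bins of exact `width` are laid left-to-right from `lo` (left-closed,
#' right-open; the last bin is clipped at `hi` if the range is not a whole
#' multiple of the width). A bin is retained iff its interval has empty
#' intersection with every exclusion interval: any overlap drops the whole
#' bin. Overlapping exclusion intervals are merged. The defaults are the
#' conventional serum settings: 0.04-ppm bins over 0.6-8.6 ppm excluding
#' 4.64-5.2 (residual water) and 5.28-6.6 ppm (noise region), which retains
#' 153 bins.
#'
#' @param lo,hi analysis range in ppm (`lo < hi`)
#' @param width bin width in ppm (> 0)
#' @param exclusions list of `c(a, b)` ppm intervals to exclude
#' @return an object of class `bin_grid` with the retained bins
#' @export
build_bin_grid <- function(lo = 0.6, hi = 8.6, width = 0.04,
                           exclusions = list(c(4.64, 5.2), c(5.28, 6.6))) {
  stopifnot(lo < hi, width > 0)
  exclusions <- .merge_intervals(exclusions)
  eps <- 1e-9
  n_full <- floor((hi - lo) / width + eps)
  left <- lo + width * (seq_len(n_full) - 1)
  right <- lo + width * seq_len(n_full)
  if (n_full == 0L || right[n_full] < hi - eps) {  # clipped final bin
    left <- c(left, lo + width * n_full)
    right <- c(right, hi)
  }
  keep <- rep(TRUE, length(left))
  for (iv in exclusions)
    keep <- keep & !(left < iv[2] - eps & right > iv[1] + eps)
  bins <- data.frame(left = left[keep], right = right[keep])
  structure(list(lo = lo, hi = hi, width = width, exclusions = exclusions,
                 bins = bins, n_total = length(left)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf(
    "Bin grid: %.3g-%.3g ppm, width %.3g ppm, %d/%d bins retained (%d excluded)\n",
    x$lo, x$hi, x$width, nrow(x$bins), x$n_total, x$n_total - nrow(x$bins)))
  invisible(x)
}

#' Bin centres of the retained bins
#' @param grid a [build_bin_grid()] object
#' @return numeric vector of bin midpoints (ppm)
#' @export
bin_centers <- function(grid) (grid$bins$left + grid$bins$right) / 2

#' Integrate a spectrum over a bin grid
#'
#' Each bin value is the trapezoidal integral of the intensity over the bin's
#' ppm interval, with linear interpolation at bin edges falling between grid
#' points. Negative intensities (noise) are integrated as-is.
#'
#' @param s an `nmr_spectrum` whose axis covers the grid's analysis range
#' @param grid a [build_bin_grid()] object
#' @return an object of class `binned_sample` (unnormalized)
#' @export
bin_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "nmr_spectrum"), inherits(grid, "bin_grid"))
  n <- length(s$ppm)
  if (s$ppm[1] > grid$lo + 1e-12 || s$ppm[n] < grid$hi - 1e-12)
    stop("spectrum does not cover the analysis range [",
         grid$lo, ", ", grid$hi, "] ppm")
  cl <- .cum_trapz_at(s$ppm, s$intensity, grid$bins$left)
  cr <- .cum_trapz_at(s$ppm, s$intensity, grid$bins$right)
  structure(list(sample_id = s$sample_id, group = s$group,
                 values = cr - cl, normalized = FALSE, grid = grid),
            class = "binned_sample")
}

#' Normalize a binned sample to percent total area
#'
#' @param b a `binned_sample` with positive total area
#' @return the sample with each value replaced by `100 * value / total`
#' @export
normalize_percent <- function(b) {
  stopifnot(inherits(b, "binned_sample"))
  total <- sum(b$values)
  if (!is.finite(total) || total <= 0)
    stop("non-positive total area: sample '", b$sample_id, "' is unusable")
  b$values <- 100 * b$values / total
  b$normalized <- TRUE
  b
}

#' Assemble normalized binned samples into a samples x bins matrix
#'
#' @param samples list of normalized `binned_sample` objects sharing one grid,
#'   with unique sample ids; row order follows input order
#' @param grid the common [build_bin_grid()]
#' @return an object of class `bin_matrix`: `grid`, `sample_id`, `group` and
#'   the numeric matrix `x` (rows = samples, columns = retained bins named by
#'   centre ppm)
#' @export
assemble_bin_matrix <- function(samples, grid) {
  if (!length(samples)) stop("no samples to assemble")
  for (b in samples) {
    stopifnot(inherits(b, "binned_sample"))
    if (!b$normalized) stop("sample '", b$sample_id, "' is not normalized")
    if (!isTRUE(all.equal(b$grid$bins, grid$bins, tolerance = 1e-12)))
      stop("mixed bin grids")
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  x <- do.call(rbind, lapply(samples, `[[`, "values"))
  rownames(x) <- ids
  colnames(x) <- sprintf("%.4f", bin_centers(grid))
  structure(list(grid = grid, sample_id = ids,
                 group = vapply(samples, `[[`, character(1), "group"),
                 x = x),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("Bin matrix: %d samples x %d bins (groups: %s)\n",
              nrow(x$x), ncol(x$x),
              paste(names(table(x$group)), table(x$group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Bin a whole cohort and assemble the normalized matrix
#'
#' Convenience wrapper: [bin_spectrum()] + [normalize_percent()] for every
#' spectrum, then [assemble_bin_matrix()].
#'
#' @param spectra list of `nmr_spectrum` objects (e.g. `cohort$spectra`)
#' @param grid a [build_bin_grid()]
#' @return a `bin_matrix`
#' @export
bin_cohort <- function(spectra, grid = build_bin_grid()) {
  binned <- lapply(spectra, function(s) normalize_percent(bin_spectrum(s, grid)))
  assemble_bin_matrix(binned, grid)
}

#' Write / read a bin matrix as a tab-separated table
#'
#' First column `sample_id`, second `group`, remaining columns named by bin
#' centre ppm (4 decimals); values at 12 significant digits. The grid
#' parameters travel in `#` header lines so the matrix re-reads bit-exactly
#' at that precision.
#'
#' @param m a `bin_matrix`
#' @param path output path
#' @return `path` invisibly (writer); a `bin_matrix` (reader)
#' @export
write_bin_matrix <- function(m, path) {
  stopifnot(inherits(m, "bin_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  excl <- paste(vapply(m$grid$exclusions,
                       function(iv) sprintf("%.17g:%.17g", iv[1], iv[2]),
                       character(1)), collapse = ",")
  writeLines(c(sprintf("# lo: %.17g", m$grid$lo),
               sprintf("# hi: %.17g", m$grid$hi),
               sprintf("# width: %.17g", m$grid$width),
               paste0("# exclusions: ", excl)), con)
  writeLines(paste(c("sample_id", "group", colnames(m$x)), collapse = "\t"), con)
  for (i in seq_len(nrow(m$x)))
    writeLines(paste(c(m$sample_id[i], m$group[i],
                       sprintf("%.12g", m$x[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_bin_matrix
#' @export
read_bin_matrix <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  val <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)[1]
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit))
  }
  excl <- lapply(strsplit(val("exclusions"), ",")[[1]], function(tok)
    as.numeric(strsplit(tok, ":")[[1]]))
  grid <- build_bin_grid(as.numeric(val("lo")), as.numeric(val("hi")),
                         as.numeric(val("width")), excl)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(x) <- tab$sample_id
  if (ncol(x) != nrow(grid$bins)) stop("column count does not match the grid")
  structure(list(grid = grid, sample_id = tab$sample_id, group = tab$group,
                 x = x),
            class = "bin_matrix")
}
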