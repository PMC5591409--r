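# Pareto scaling: centre each column and divide by the square root of its
# sample standard deviation -- the conventional compromise between unit
# variance and no scaling for NMR bin tables.

.as_matrix <- function(m) {
  if (inherits(m, "bin_matrix")) m$x
  else if (is.matrix(m)) m
  else stop("expected a bin_matrix or a numeric matrix")
}

#' Pareto-scale a bin matrix
#'
#' Each column j is transformed as `(x - mean_j) / sqrt(s_j)` with `s_j` the
#' sample standard deviation (n-1 denominator). Columns with zero variance
#' are centred only (divisor 1) and flagged.
#'
#' @param m a `bin_matrix` or numeric matrix with >= 2 rows
#' @return list with `x` (the scaled matrix, class `scaled_matrix`) and
#'   `model` (a `scaling_model`: per-column means, SDs, divisors, zero-variance
#'   flags)
#' @export
pareto_scale <- function(m) {
  x <- .as_matrix(m)
  if (nrow(x) < 2L) stop("Pareto scaling needs at least 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv <= .Machine$double.eps * pmax(abs(mu), 1)
  divisor <- ifelse(zero, 1, sqrt(sdv))
  xs <- sweep(sweep(x, 2, mu, "-"), 2, divisor, "/")
  model <- structure(list(mean = mu, sd = sdv, divisor = divisor,
                          zero_variance = zero, mode = "pareto"),
                     class = "scaling_model")
  attr(xs, "groups") <- if (inherits(m, "bin_matrix")) m$group else NULL
  class(xs) <- c("scaled_matrix", class(xs))
  list(x = xs, model = model)
}

#' Apply a fitted scaling model to new data
#'
#' Uses the training means and divisors, never the new data's own moments
#' (required for leakage-free cross-validation).
#'
#' @param model a `scaling_model` from [pareto_scale()]
#' @param m new `bin_matrix` or numeric matrix with matching columns
#' @return the scaled matrix
#' @export
apply_scaling <- function(model, m) {
  stopifnot(inherits(model, "scaling_model"))
  x <- .as_matrix(m)
  if (ncol(x) != length(model$mean))
    stop("dimension mismatch: model has ", length(model$mean),
         " columns, data has ", ncol(x))
  xs <- sweep(sweep(x, 2, model$mean, "-"), 2, model$divisor, "/")
  class(xs) <- c("scaled_matrix", class(xs))
  xs
}
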