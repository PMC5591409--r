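# Internal numerical helpers shared across modules.

.norm_vec <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

# strict monotone + uniform spacing check (relative tolerance on the spacing)
.is_uniform_ascending <- function(x, rtol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  if (any(d <= 0)) return(FALSE)
  h <- mean(d)
  all(abs(d - h) <= rtol * abs(h) + 1e-15)
}

# Cumulative trapezoidal integral of the piecewise-linear interpolant of
# (x, y), evaluated exactly at arbitrary points `at` (linear interpolation of
# y inside a grid segment makes the partial-segment contribution a trapezoid).
.cum_trapz_at <- function(x, y, at) {
  n <- length(x)
  if (any(at < x[1] - 1e-12) || any(at > x[n] + 1e-12))
    stop("integration point outside the spectrum axis")
  at <- pmin(pmax(at, x[1]), x[n])
  cum <- c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
  i <- findInterval(at, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  dx <- at - x[i]
  yi <- y[i] + dx / (x[i + 1L] - x[i]) * (y[i + 1L] - y[i])
  cum[i] + dx * (y[i] + yi) / 2
}

# trapezoidal integral of (x, y) over [a, b] with edge interpolation
.integrate_interval <- function(x, y, a, b) {
  if (b <= a) return(0)
  v <- .cum_trapz_at(x, y, c(a, b))
  v[2] - v[1]
}

# evaluate a polynomial with coefficients coef (ascending powers) at x
.eval_poly <- function(coef, x) {
  out <- numeric(length(x))
  for (k in seq_along(coef)) out <- out + coef[k] * x^(k - 1)
  out
}

# unit-area Lorentzian line scaled to `area`
.lorentz <- function(x, center, hwhm, area) {
  (area / pi) * hwhm / ((x - center)^2 + hwhm^2)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

.stopifnot_prob <- function(p, what = "p-values") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop(what, " must lie in [0, 1]")
  invisible(p)
}
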