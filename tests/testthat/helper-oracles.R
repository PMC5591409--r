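# Independent oracles (brute force / closed form) and small fixtures shared
# across the suite. Oracles are deliberately written from first principles,
# separately from the package's code paths.

oracle_trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group labelings of the pooled (tie-free) values; the tie-free null U
# distribution is symmetric about n1*n2/2, so the two-sided p is the mass at
# least as far from the centre as observed
oracle_mw_exact_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  labelings <- utils::combn(length(pool), n1)
  u_all <- apply(labelings, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Holm step-down by the textbook loop: sort ascending, running max of
# (m - i + 1) * p_(i), cap at 1, return in input order
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# count retained bins by direct enumeration of bin intervals vs exclusions
oracle_bin_count <- function(lo, hi, width, exclusions) {
  eps <- 1e-9
  lefts <- c()
  l <- lo
  while (l < hi - eps) {
    lefts <- c(lefts, l)
    l <- l + width
  }
  rights <- pmin(lefts + width, hi)
  keep <- mapply(function(a, b) {
    !any(vapply(exclusions,
                function(iv) a < iv[2] - eps && b > iv[1] + eps,
                logical(1)))
  }, lefts, rights)
  sum(keep)
}

# single-component PLS1 written out from first principles
oracle_pls1_component <- function(x, yc) {
  w <- drop(crossprod(x, yc))
  w <- w / sqrt(sum(w^2))
  t_ <- drop(x %*% w)
  cc <- sum(t_ * yc) / sum(t_^2)
  list(w = w, t = t_, c = cc,
       r2y = 1 - sum((yc - t_ * cc)^2) / sum(yc^2))
}

tsp_reference_spec <- function() {
  ref <- metabolite_spec("TSP", list(multiplet(0, 1, J = 0, protons = 9)),
                         distributions = list(),
                         quant = list(multiplet = 1, margin = 0.05,
                                      overlap = FALSE))
  ref$concentration <- 0.507
  ref
}

# two-metabolite library (lactate + acetone, C/NR classes) for fast renders
tiny_library <- function() {
  metabolite_library(
    list(
      metabolite_spec("lactate",
                      list(multiplet(1.33, 2, J = 6.9, protons = 3)),
                      list(C = list(mean = 1.88, sd = 0.04, source = "paper"),
                           NR = list(mean = 1.16, sd = 0.05, source = "paper")),
                      quant = list(multiplet = 1, margin = 0.05,
                                   overlap = FALSE)),
      metabolite_spec("acetone",
                      list(multiplet(2.23, 1, J = 0, protons = 6)),
                      list(C = list(mean = 0.0008, sd = 0.001,
                                    source = "paper"),
                           NR = list(mean = 0.02, sd = 0.01,
                                     source = "paper")),
                      quant = list(multiplet = 1, margin = 0.02,
                                   overlap = FALSE))),
    tsp_reference_spec())
}

# quiet acquisition: no noise, jitter, water or baseline
clean_acq <- function(...) {
  acquisition_params(noise_sd = 0, shift_jitter_sd = 0, water_area = 0, ...)
}

# balanced two-class gaussian matrix with one informative column
planted_matrix <- function(n = 40, p = 10, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + effect * (y == "B")
  list(x = x, y = y)
}
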