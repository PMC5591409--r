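# Model validation: label-permutation diagnostics (R2/Q2 vs label correlation,
# with intercepts at zero correlation) and CV-ANOVA significance.

#' Permutation test with R2/Q2 intercept diagnostics
#'
#' Refits the discriminant model `n_perm` times under randomly shuffled class
#' labels, recording for each permutation the absolute Pearson correlation
#' `r` between permuted and original (centred) labels, the refit `R2Y`, and
#' the cross-validated `Q2`. Least-squares lines of `R2Y` vs `r` and `Q2` vs
#' `r` are fitted over all permuted records plus the unpermuted anchor
#' (`r = 1`); their values at `r = 0` are the reported intercepts. Following
#' the usual convention the permutation refits use the corresponding PLS-DA
#' model with the same total component count; `method = "opls"` refits the
#' OPLS-DA instead.
#'
#' @param m unscaled `bin_matrix` or numeric matrix
#' @param y two-class label vector
#' @param n_orth orthogonal components of the reference model (total
#'   components = `1 + n_orth`)
#' @param n_perm number of permutations
#' @param seed RNG seed for the shuffles (caller's RNG state is preserved)
#' @param folds cross-validation folds
#' @param method model refit inside the permutations: `"pls"` (default) or
#'   `"opls"`
#' @return an object of class `permutation_summary`: `records` (data.frame
#'   `perm`, `r`, `R2Y`, `Q2`; perm 0 is the anchor), fitted `slopes`,
#'   `r2_intercept`, `q2_intercept`, empirical `p_r2`/`p_q2`
#'   (`P(stat_perm >= stat_model)` with the +1 correction), and the anchor
#'   statistics
#' @export
permutation_test <- function(m, y, n_orth = 1, n_perm = 500, seed = 1,
                             folds = 7, method = c("pls", "opls")) {
  method <- match.arg(method)
  x <- .as_matrix(m)
  y <- as.character(y)
  stopifnot(n_perm >= 1)
  if (length(unique(y)) < 2L) stop("constant y cannot be permuted")
  code <- .code_classes(y)
  yc0 <- code$y01 - mean(code$y01)

  fit_once <- function(labels) {
    sc <- pareto_scale(x)
    r2y <- if (method == "opls")
      fit_oplsda(sc$x, labels, n_orth = n_orth)$R2Y
    else
      fit_pls1(sc$x, labels, ncomp = 1 + n_orth)$R2Y
    q2 <- cross_validate_q2(x, labels, n_orth = n_orth, folds = folds,
                            method = method)$q2
    c(R2Y = r2y, Q2 = q2)
  }

  anchor <- fit_once(y)
  records <- .with_seed(seed, {
    out <- matrix(NA_real_, n_perm, 3,
                  dimnames = list(NULL, c("r", "R2Y", "Q2")))
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      ypc <- as.numeric(yp == code$levels[2]) - mean(code$y01)
      stat <- fit_once(yp)
      out[i, ] <- c(abs(stats::cor(yc0, ypc)), stat)
    }
    out
  })
  rec <- data.frame(perm = 0:n_perm,
                    r = c(1, records[, "r"]),
                    R2Y = c(anchor["R2Y"], records[, "R2Y"]),
                    Q2 = c(anchor["Q2"], records[, "Q2"]))
  line <- function(v) {  # least-squares fit of v ~ r over anchor + perms
    r <- rec$r
    slope <- sum((r - mean(r)) * (v - mean(v))) / sum((r - mean(r))^2)
    c(slope = slope, intercept = mean(v) - slope * mean(r))
  }
  l_r2 <- line(rec$R2Y); l_q2 <- line(rec$Q2)
  structure(list(records = rec,
                 slopes = c(R2Y = unname(l_r2["slope"]),
                            Q2 = unname(l_q2["slope"])),
                 r2_intercept = unname(l_r2["intercept"]),
                 q2_intercept = unname(l_q2["intercept"]),
                 p_r2 = (1 + sum(records[, "R2Y"] >= anchor["R2Y"])) /
                   (n_perm + 1),
                 p_q2 = (1 + sum(records[, "Q2"] >= anchor["Q2"])) /
                   (n_perm + 1),
                 anchor = anchor, n_perm = n_perm, seed = seed,
                 method = method),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%d permutations, %s refits): R2 intercept %.3f, Q2 intercept %.3f\n",
    x$n_perm, toupper(x$method), x$r2_intercept, x$q2_intercept))
  cat(sprintf("  empirical P(R2_perm >= R2_model) = %.4g, P(Q2_perm >= Q2_model) = %.4g\n",
              x$p_r2, x$p_q2))
  cat(sprintf("  heuristic: R2 intercept < 0.4 %s; Q2 intercept < 0.05 %s\n",
              ifelse(x$r2_intercept < 0.4, "ok", "EXCEEDED"),
              ifelse(x$q2_intercept < 0.05, "ok", "EXCEEDED")))
  invisible(x)
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test comparing the cross-validated predictive variation with the
#' predictive residuals: `F = ((SS - PRESS)/A) / (PRESS/(N - 1 - A))` with
#' `A` the number of model components and `N` the number of samples; the
#' p-value is the upper-tail F(A, N-1-A) probability. `PRESS > SS` gives a
#' negative F and is reported as p = 1.
#'
#' @param cv a `cv_result` from [cross_validate_q2()]
#' @param A number of components (default: the cross-validated model's)
#' @param N number of samples (default: taken from `cv`)
#' @return an object of class `cv_anova`: `ss_total`, `press`, `ss_reg`,
#'   `df_reg`, `df_res`, `F`, `p`
#' @export
cv_anova <- function(cv, A = NULL, N = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  if (anyNA(cv$yhat)) stop("PRESS undefined: cross-validation incomplete")
  if (is.null(A)) A <- cv$n_components
  if (is.null(N)) N <- length(cv$yhat)
  if (N <= A + 1) stop("need N > A + 1 samples")
  ss <- cv$ss; press <- cv$press
  Fstat <- ((ss - press) / A) / (press / (N - 1 - A))
  p <- if (Fstat <= 0) 1 else stats::pf(Fstat, A, N - 1 - A,
                                        lower.tail = FALSE)
  structure(list(ss_total = ss, press = press, ss_reg = ss - press,
                 df_reg = A, df_res = N - 1 - A, F = Fstat, p = p),
            class = "cv_anova")
}

#' @export
print.cv_anova <- function(x, ...) {
  cat(sprintf("CV-ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_reg, x$df_res, x$F, x$p))
  invisible(x)
}
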