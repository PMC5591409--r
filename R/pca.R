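# PCA by singular-value decomposition of the scaled matrix, used as the
# unsupervised outlier screen (Hotelling T2) before any supervised modelling.

#' Principal components analysis of a scaled matrix
#'
#' SVD-based PCA: successive variance-maximizing orthogonal components with
#' scores `X v` and per-component explained-variance fraction
#' `(score sum of squares) / (total sum of squares of X)`.
#'
#' @param x a `scaled_matrix` (already centred) or numeric matrix
#' @param n_comp number of components (default `min(n - 1, p)`)
#' @return an object of class `pca_model`: `scores`, `loadings`, `explained`,
#'   `n`, `total_ss`
#' @export
fit_pca <- function(x, n_comp = NULL) {
  x <- unclass(x)
  stopifnot(is.matrix(x))
  n <- nrow(x); p <- ncol(x)
  max_comp <- min(n - 1L, p)
  if (is.null(n_comp)) n_comp <- max_comp
  if (n_comp > max_comp) stop("n_comp exceeds min(rows - 1, cols)")
  sv <- svd(x, nu = n_comp, nv = n_comp)
  scores <- sv$u %*% diag(sv$d[seq_len(n_comp)], n_comp, n_comp)
  colnames(scores) <- paste0("PC", seq_len(n_comp))
  structure(list(scores = scores,
                 loadings = sv$v,
                 explained = sv$d[seq_len(n_comp)]^2 / sum(sv$d^2),
                 n = n, total_ss = sum(x^2)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", ncol(x$scores), "components; explained fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Hotelling T2 outlier screen on PCA scores
#'
#' Per-sample `T2_i = sum_a t_ia^2 / var(t_a)`, compared with the critical
#' limit `A (N^2 - 1) / (N (N - A)) F_{1-alpha}(A, N - A)`. Report-only: no
#' sample is removed.
#'
#' @param pca a fitted [fit_pca()] model
#' @param alpha significance level of the limit
#' @return data.frame with `t2`, the shared `limit` and a logical `outlier`
#'   flag per sample
#' @export
score_outliers <- function(pca, alpha = 0.05) {
  stopifnot(inherits(pca, "pca_model"), alpha > 0, alpha <= 1)
  A <- ncol(pca$scores); N <- pca$n
  if (N <= A) stop("need more samples than components for the T2 limit")
  s2 <- apply(pca$scores, 2, stats::var)
  t2 <- rowSums(sweep(pca$scores^2, 2, s2, "/"))
  limit <- A * (N^2 - 1) / (N * (N - A)) * stats::qf(1 - alpha, A, N - A)
  data.frame(sample = seq_len(N), t2 = t2, limit = limit,
             outlier = t2 > limit)
}
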