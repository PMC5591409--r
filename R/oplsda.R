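# Two-class (O)PLS-DA. The response is the 0/1 class dummy, centred; the
# orthogonal filter removes y-orthogonal structured variation from X before a
# single predictive component is extracted (1 predictive + n_orth orthogonal
# components, "1P + nO").

.code_classes <- function(y) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("exactly 2 classes required, got ", length(lev), ": ",
         paste(lev, collapse = ", "))
  if (any(table(y) < 2L)) stop("each class needs at least 2 samples")
  list(levels = lev, y01 = as.numeric(y == lev[2]))
}

#' Fit a two-class OPLS-DA model
#'
#' The class labels are coded 0/1 and centred. For each orthogonal component
#' on the current (filtered) X: `w = normalize(X'y)`, `t = X w`,
#' `p = X't / (t't)`, `w_o = normalize(p - (w'p) w)`, `t_o = X w_o`,
#' `p_o = X't_o / (t_o't_o)`, `X <- X - t_o p_o'`; then one predictive
#' component is extracted from the filtered X. `R2Y = 1 - |y - t c|^2 / |y|^2`
#' and `R2X(cum)` sums `|t p'|^2 / |X0|^2` over all (predictive + orthogonal)
#' components. The cross-validated `Q2` is not computed here; see
#' [cross_validate_q2()].
#'
#' @param x scaled (centred) numeric matrix, samples in rows
#' @param y two-class label vector (factor or character), one per row
#' @param n_orth number of orthogonal components (>= 0)
#' @return an object of class `oplsda`: predictive weight `w` (unit norm),
#'   score `t`, loading `p`, y-loading `c`, orthogonal `W_o`/`T_o`/`P_o`,
#'   `R2X`, `R2Y`, `Q2` (NA until cross-validated), class `levels`, `y_mean`,
#'   component spec string
#' @export
fit_oplsda <- function(x, y, n_orth = 1) {
  x <- unclass(x)
  stopifnot(is.matrix(x), nrow(x) == length(y), n_orth >= 0)
  code <- .code_classes(y)
  yc <- code$y01 - mean(code$y01)
  x0_ss <- sum(x^2)
  p_dim <- ncol(x)
  W_o <- matrix(0, p_dim, 0); T_o <- matrix(0, nrow(x), 0)
  P_o <- matrix(0, p_dim, 0)
  r2x_comp <- numeric(0)
  X <- x
  n_orth_used <- 0L
  for (k in seq_len(n_orth)) {
    w <- .norm_vec(drop(crossprod(X, yc)))
    t_ <- drop(X %*% w)
    p <- drop(crossprod(X, t_)) / sum(t_^2)
    w_o <- p - sum(w * p) * w
    if (sqrt(sum(w_o^2)) < 1e-10) {
      warning("no y-orthogonal variation left after ", k - 1,
              " orthogonal component(s)")
      break
    }
    w_o <- .norm_vec(w_o)
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    r2x_comp <- c(r2x_comp, sum(t_o^2) * sum(p_o^2) / x0_ss)
    n_orth_used <- k
  }
  w <- .norm_vec(drop(crossprod(X, yc)))
  t_ <- drop(X %*% w)
  p <- drop(crossprod(X, t_)) / sum(t_^2)
  cc <- sum(t_ * yc) / sum(t_^2)
  r2y <- 1 - sum((yc - t_ * cc)^2) / sum(yc^2)
  r2x_comp <- c(sum(t_^2) * sum(p^2) / x0_ss, r2x_comp)
  structure(list(levels = code$levels, y_mean = mean(code$y01),
                 w = w, t = t_, p = p, c = cc,
                 W_o = W_o, T_o = T_o, P_o = P_o,
                 n_orth = n_orth_used,
                 R2X = sum(r2x_comp), R2X_comp = r2x_comp,
                 R2Y = r2y, Q2 = NA_real_,
                 components = sprintf("1P + %dO", n_orth_used),
                 ssy = sum(yc^2)),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA %s vs %s | components %s | R2X %.3f  R2Y %.3f  Q2 %s\n",
    x$levels[1], x$levels[2], x$components, x$R2X, x$R2Y,
    if (is.na(x$Q2)) "(not cross-validated)" else sprintf("%.3f", x$Q2)))
  invisible(x)
}

#' Predict from a fitted OPLS-DA model
#'
#' Applies the stored orthogonal filter to the new (identically scaled) data,
#' scores it on the predictive component and decodes class calls with a 0.5
#' threshold on the predicted 0/1 response.
#'
#' @param model a fitted [fit_oplsda()] model
#' @param newx scaled matrix with the same columns as the training data
#' @return list with `scores` (predictive), `t_orth`, `yhat` (on the 0/1
#'   scale) and `class` calls
#' @export
predict_oplsda <- function(model, newx) {
  X <- unclass(newx)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$w))
    stop("dimension mismatch: model has ", length(model$w), " columns")
  t_orth <- matrix(0, nrow(X), ncol(model$W_o))
  for (k in seq_len(ncol(model$W_o))) {
    t_o <- drop(X %*% model$W_o[, k])
    X <- X - tcrossprod(t_o, model$P_o[, k])
    t_orth[, k] <- t_o
  }
  t_ <- drop(X %*% model$w)
  yhat <- t_ * model$c + model$y_mean
  list(scores = t_, t_orth = t_orth, yhat = yhat,
       class = model$levels[(yhat > 0.5) + 1L])
}

#' Fit a PLS1 model (NIPALS, single response)
#'
#' Standard NIPALS PLS1 with component-wise deflation of X and y; the
#' response is the centred 0/1 class dummy. Used for the permutation
#' diagnostics (refits on the corresponding PLS-DA model) and as the
#' reduction target of OPLS-DA with zero orthogonal components.
#'
#' @param x scaled (centred) numeric matrix
#' @param y two-class label vector
#' @param ncomp number of components
#' @return an object of class `pls1`: per-component `W`, `P`, `c`, scores
#'   `T`, `R2Y` (cumulative), class `levels`, `y_mean`
#' @export
fit_pls1 <- function(x, y, ncomp = 2) {
  X <- unclass(x)
  stopifnot(is.matrix(X), nrow(X) == length(y), ncomp >= 1)
  code <- .code_classes(y)
  yc <- code$y01 - mean(code$y01)
  ssy0 <- sum(yc^2)
  W <- P <- matrix(0, ncol(X), 0)
  Tm <- matrix(0, nrow(X), 0)
  cs <- numeric(0)
  for (a in seq_len(ncomp)) {
    xy <- drop(crossprod(X, yc))
    if (sqrt(sum(xy^2)) < 1e-12) break
    w <- .norm_vec(xy)
    t_ <- drop(X %*% w)
    p <- drop(crossprod(X, t_)) / sum(t_^2)
    cc <- sum(t_ * yc) / sum(t_^2)
    X <- X - tcrossprod(t_, p)
    yc <- yc - t_ * cc
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t_)
    cs <- c(cs, cc)
  }
  structure(list(levels = code$levels, y_mean = mean(code$y01),
                 W = W, P = P, T = Tm, c = cs,
                 R2Y = 1 - sum(yc^2) / ssy0),
            class = "pls1")
}

#' @rdname fit_pls1
#' @param model a fitted `pls1` model
#' @param newx scaled matrix with matching columns
#' @export
predict_pls1 <- function(model, newx) {
  X <- unclass(newx)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(model$W)) stop("dimension mismatch")
  yhat <- rep(model$y_mean, nrow(X))
  for (a in seq_along(model$c)) {
    t_ <- drop(X %*% model$W[, a])
    X <- X - tcrossprod(t_, model$P[, a])
    yhat <- yhat + t_ * model$c[a]
  }
  list(yhat = yhat, class = model$levels[(yhat > 0.5) + 1L])
}

#' Cross-validated Q2 for a two-class (O)PLS-DA model
#'
#' Deterministic interleaved folds (sample index mod `folds` after ordering
#' by class then position) so results are seed-free. Within each fold the
#' scaling model is refit on the training rows only, the model refit, and the
#' held-out rows predicted. `Q2 = 1 - PRESS / SS` with
#' `PRESS = sum (y_i - yhat_i,out-of-fold)^2` and `SS` the corrected sum of
#' squares of the 0/1 response.
#'
#' @param m unscaled `bin_matrix` or numeric matrix
#' @param y two-class label vector
#' @param n_orth orthogonal components for `method = "opls"`; for
#'   `method = "pls"` the total component count is `1 + n_orth`
#' @param folds number of folds (2..n; `folds = n` is leave-one-out)
#' @param method refit an OPLS-DA or a PLS-DA model inside the folds
#' @return an object of class `cv_result`: `fold`, out-of-fold `yhat`,
#'   `press`, `ss`, `q2`, `n_components`
#' @export
cross_validate_q2 <- function(m, y, n_orth = 1, folds = 7,
                              method = c("opls", "pls")) {
  method <- match.arg(method)
  x <- .as_matrix(m)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), folds >= 2, folds <= nrow(x))
  code <- .code_classes(y)
  y01 <- code$y01
  ord <- order(y, seq_along(y))
  fold <- integer(length(y))
  fold[ord] <- (seq_along(y) - 1L) %% folds + 1L
  yhat <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("invalid split: fold ", f, " leaves a single class in training")
    sc <- pareto_scale(x[tr, , drop = FALSE])
    xte <- apply_scaling(sc$model, x[!tr, , drop = FALSE])
    if (method == "opls") {
      fit <- fit_oplsda(sc$x, y[tr], n_orth = n_orth)
      yhat[!tr] <- predict_oplsda(fit, xte)$yhat
    } else {
      fit <- fit_pls1(sc$x, y[tr], ncomp = 1 + n_orth)
      yhat[!tr] <- predict_pls1(fit, xte)$yhat
    }
  }
  press <- sum((y01 - yhat)^2)
  ss <- sum((y01 - mean(y01))^2)
  structure(list(fold = fold, yhat = yhat, y01 = y01,
                 press = press, ss = ss, q2 = 1 - press / ss,
                 n_components = 1L + as.integer(n_orth), method = method),
            class = "cv_result")
}
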