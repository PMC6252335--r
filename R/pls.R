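#' Two-block partial least squares regression (NIPALS)
#'
#' Decomposes predictor and response blocks into pairs of latent variables
#' chosen to maximize covariance, deflating both blocks after each pair.
#' No scaling is applied (coordinates of a Procrustes-aligned shape share
#' one unit); both blocks are centered internally. Used both for the
#' offspring-on-father heritability regressions and for covariate
#' adjustment.
#'
#' @param X n x p predictor matrix.
#' @param Y n x q response matrix (a vector is treated as one column).
#' @param ncomp number of latent component pairs; at most `min(n - 1, p)`.
#' @param tol NIPALS inner-loop convergence tolerance.
#' @return object of class `plsr_model`: weights `W` (p x a), predictor
#'   loadings `P`, response loadings `C` (q x a), scores `Ts` (n x a),
#'   per-pair score covariances `covariances`, centered means, the
#'   coefficient array and the per-component training MSE curve `mse`.
#' @export
plsr_fit <- function(X, Y, ncomp, tol = 1e-12) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3L) stop("need at least 3 observations")
  if (ncomp > min(n - 1L, p)) stop("ncomp exceeds min(n - 1, p)")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  X0 <- Xc; Y0 <- Yc
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Ts <- matrix(0, n, ncomp)
  covariances <- numeric(ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    if (sum(Xc^2) < 1e-300 || sum(Yc^2) < 1e-300) break
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- crossprod(Xc, u)
    t_old <- rep(Inf, n)
    for (it in seq_len(500L)) {
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
      u <- drop(Yc %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
      w <- crossprod(Xc, u)
    }
    if (sum(tt^2) < 1e-300) break
    a <- a + 1L
    pp <- drop(crossprod(Xc, tt)) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Ts[, a] <- tt
    # covariance attained by the unit-norm weight pair (w, c)
    covariances[a] <- abs(sum(tt * (Yc %*% cc))) / (sqrt(sum(cc^2)) * n)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, cc)
  }
  if (a == 0L) stop("predictor or response block has no variance")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  C <- C[, seq_len(a), drop = FALSE]; Ts <- Ts[, seq_len(a), drop = FALSE]
  # coefficients and training MSE for every truncation 1..a
  B <- array(0, c(p, q, a))
  mse <- numeric(a)
  R <- W %*% solve(crossprod(P, W))   # modified weights: X0 %*% R = Ts
  for (k in seq_len(a)) {
    B[, , k] <- R[, seq_len(k), drop = FALSE] %*% t(C[, seq_len(k), drop = FALSE])
    mse[k] <- mean((Y0 - X0 %*% B[, , k])^2)
  }
  structure(
    list(W = W, P = P, C = C, Ts = Ts, coefficients = B,
         covariances = covariances[seq_len(a)], mse = mse,
         ncomp = a, x_mean = xm, y_mean = ym, n = n, p = p, q = q),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", x$ncomp, " latent pairs; p = ", x$p, ", q = ", x$q,
      ", n = ", x$n, "; training MSE = ",
      format(x$mse[x$ncomp], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS regression
#'
#' @param object a `plsr_model`.
#' @param newdata matrix with `p` columns.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return fitted response matrix.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncomp < 1L || ncomp > object$ncomp) stop("ncomp out of range")
  Xc <- sweep(newdata, 2L, object$x_mean)
  sweep(Xc %*% object$coefficients[, , ncomp], 2L, object$y_mean, "+")
}

#' @export
fitted.plsr_model <- function(object, ...) {
  sweep(object$Ts %*% t(object$C), 2L, object$y_mean, "+")
}

#' Broom-style tidier for a PLS regression
#' @param x a `plsr_model`.
#' @param ... unused.
#' @return tibble with one row per latent pair: score covariance,
#'   cumulative training MSE.
#' @method tidy plsr_model
#' @export
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$ncomp),
                 score_covariance = x$covariances,
                 mse = x$mse)
}

#' @method glance plsr_model
#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, p = x$p, q = x$q,
                 mse = x$mse[x$ncomp])
}

#' Choose the PLS component count by k-fold cross-validated MSE
#'
#' Folds are assigned deterministically by interleaving row indices, so
#' the choice depends only on the data. The selected count minimizes the
#' cross-validated mean squared prediction error.
#'
#' @param X,Y data blocks.
#' @param max_ncomp largest count to consider (capped at `min(n - 1 -
#'   ceiling(n / folds), p)` so every training fold can support it).
#' @param folds number of folds (default 5).
#' @return list with `ncomp` (the minimizer) and `cv_mse` (the curve).
#' @export
cv_ncomp <- function(X, Y, max_ncomp, folds = 5L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold_id <- rep_len(seq_len(folds), n)
  cap <- min(max_ncomp, n - 1L - ceiling(n / folds), ncol(X))
  if (cap < 1L) return(list(ncomp = 1L, cv_mse = NA_real_))
  press <- matrix(NA_real_, folds, cap)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- plsr_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp = cap)
    for (k in seq_len(fit$ncomp)) {
      pred <- predict(fit, X[!tr, , drop = FALSE], ncomp = k)
      press[f, k] <- sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
  }
  cv_mse <- colSums(press) / (n * ncol(Y))
  cv_mse[is.na(cv_mse)] <- Inf
  list(ncomp = which.min(cv_mse), cv_mse = cv_mse)
}

# ---- fast cross-product PLS (kernel algorithm) ----------------------------
# Computes the PLS regression coefficient matrix from crossproducts only;
# used in permutation loops where X^T X is permutation-invariant.
# Returns list(B, sse) given XtX (p x p), XtY (p x q), ssy (total SS of Y).
pls_kernel_coef <- function(XtX, XtY, ncomp) {
  p <- nrow(XtX); q <- ncol(XtY)
  Rm <- matrix(0, p, ncomp); Pm <- matrix(0, p, ncomp)
  B <- matrix(0, p, q)
  XtY_work <- XtY
  for (a in seq_len(ncomp)) {
    if (sum(XtY_work^2) < 1e-300) break
    if (q == 1L) w <- XtY_work[, 1L] else w <- svd(XtY_work, nu = 1L, nv = 0L)$u[, 1L]
    w <- w / sqrt(sum(w^2))
    r <- w
    if (a > 1L) {
      jj <- seq_len(a - 1L)
      r <- w - Rm[, jj, drop = FALSE] %*% crossprod(Pm[, jj, drop = FALSE], w)
    }
    XtXr <- XtX %*% r
    tt <- drop(crossprod(r, XtXr))
    if (tt < 1e-300) break
    pp <- XtXr / tt
    qq <- drop(crossprod(XtY_work, r)) / tt
    Rm[, a] <- r; Pm[, a] <- pp
    B <- B + tcrossprod(r, qq)
    XtY_work <- XtY_work - XtXr %*% t(qq)
  }
  B
}

# h2 from crossproducts for a fixed component count; signed like
# estimate_h2 when the blocks share a dimension (see estimate_h2)
h2_from_crossprod <- function(XtX, XtY, ssx, ssy, ncomp) {
  B <- pls_kernel_coef(XtX, XtY, ncomp)
  sse <- ssy - 2 * sum(B * XtY) + sum(B * (XtX %*% B))
  r2 <- 1 - sse / ssy
  if (r2 < 0) r2 <- 0
  if (r2 > 1) r2 <- 1
  sgn <- if (nrow(XtY) == ncol(XtY) && sum(diag(XtY)) < 0) -1 else 1
  sgn * 2 * sqrt(r2 * ssy / ssx)
}
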