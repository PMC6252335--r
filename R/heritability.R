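#' Multivariate shape coefficient of determination
#'
#' The fraction of shape variance explained by a prediction, defined in
#' terms of squared deviations in the aligned shape space:
#' `1 - sum_i ||y_i - yhat_i||^2 / sum_i ||y_i - ybar||^2`. Collapses to
#' the classical R-squared when the response is univariate. Negative
#' values (a predictor worse than the mean shape) are clipped to 0 with a
#' warning.
#'
#' @param y_true,y_pred matrices of identical dimension (rows = subjects).
#' @return scalar in `[0, 1]`.
#' @export
shape_r2 <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  stopifnot(all(dim(y_true) == dim(y_pred)))
  sst <- sum(sweep(y_true, 2L, colMeans(y_true))^2)
  if (sst <= 0) stop("response block has zero total variance")
  r2 <- 1 - sum((y_true - y_pred)^2) / sst
  if (r2 < 0) {
    warning("negative shape R-squared clipped to 0")
    r2 <- 0
  }
  min(r2, 1)
}

#' Transform a shape R-squared to a multivariate regression coefficient
#'
#' `b = sqrt(r2 * ss_offspring / ss_parent)`, the multivariate
#' generalization consistent with the univariate identity
#' `b = r * s_y / s_x`; the sign is fixed positive.
#'
#' @param r_squared shape coefficient of determination in `[0, 1]`.
#' @param ss_parent,ss_offspring total (centered) sums of squares of the
#'   parent and offspring blocks; `ss_parent` must be positive.
#' @return non-negative regression coefficient.
#' @export
r2_to_b <- function(r_squared, ss_parent, ss_offspring) {
  if (ss_parent <= 0) stop("ss_parent must be positive")
  sqrt(r_squared * ss_offspring / ss_parent)
}

#' Estimate narrow-sense heritability from paired parent-offspring blocks
#'
#' Fits a PLS regression of the offspring block on the father block,
#' computes the multivariate shape R-squared of the fit, transforms it to
#' a regression coefficient `b`, and reports `h2 = 2 b` — the
#' parent-offspring estimator for a one-parent one-offspring design under
#' purely additive inheritance. Estimates are reported raw: values above
#' 1 (or 2 in degenerate self-regression) are not truncated. When the
#' two blocks have the same dimension (paired coordinates or a shared PC
#' basis) the estimate carries the sign of the trace of the
#' cross-covariance, so that estimates under a broken pairing center at
#' zero instead of piling up at small positive values; magnitudes are
#' unchanged.
#'
#' @param fathers n x p matrix of father shape variables (paired rows).
#' @param offspring n x q matrix of offspring shape variables.
#' @param ncomp latent component count; `NULL` (default) picks the count
#'   minimizing 5-fold cross-validated MSE, capped at
#'   `min(max_ncomp, n - 1, p)`.
#' @param max_ncomp cap on the candidate component count (default 15).
#' @return object of class `herit_estimate` with `r_squared`, `b`, `h2`,
#'   `mse` (training MSE at the chosen count), `ncomp`, `n`, `cv_mse`.
#' @export
estimate_h2 <- function(fathers, offspring, ncomp = NULL, max_ncomp = 15L) {
  X <- as.matrix(fathers); Y <- as.matrix(offspring)
  n <- nrow(X)
  if (nrow(Y) != n) stop("father and offspring blocks must be paired (same rows)")
  if (n < 10L) stop("need at least 10 pairs")
  cv <- NULL
  if (is.null(ncomp)) {
    cv <- cv_ncomp(X, Y, max_ncomp = min(max_ncomp, n - 1L, ncol(X)))
    ncomp <- cv$ncomp
  }
  fit <- plsr_fit(X, Y, ncomp = min(ncomp, n - 1L, ncol(X)))
  yhat <- fitted(fit)
  r2 <- shape_r2(Y, yhat)
  Xc <- sweep(X, 2L, colMeans(X)); Yc <- sweep(Y, 2L, colMeans(Y))
  ssx <- sum(Xc^2)
  ssy <- sum(Yc^2)
  sgn <- 1
  if (ncol(X) == ncol(Y)) {
    tr <- sum(Xc * Yc)  # trace of the cross-covariance
    if (tr < 0) sgn <- -1
  }
  b <- sgn * r2_to_b(r2, ssx, ssy)
  structure(
    list(r_squared = r2, b = b, h2 = 2 * b, mse = fit$mse[fit$ncomp],
         ncomp = fit$ncomp, n = n, ss_parent = ssx, ss_offspring = ssy,
         cv_mse = if (is.null(cv)) NULL else cv$cv_mse, model = fit),
    class = "herit_estimate"
  )
}

#' @export
print.herit_estimate <- function(x, ...) {
  cat("<herit_estimate> h2 = ", format(x$h2, digits = 4),
      " (R2 = ", format(x$r_squared, digits = 4),
      ", b = ", format(x$b, digits = 4),
      ", ncomp = ", x$ncomp, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @method tidy herit_estimate
#' @export
tidy.herit_estimate <- function(x, ...) {
  tibble::tibble(term = c("r_squared", "b", "h2"),
                 estimate = c(x$r_squared, x$b, x$h2))
}

#' @method glance herit_estimate
#' @export
glance.herit_estimate <- function(x, ...) {
  tibble::tibble(h2 = x$h2, r_squared = x$r_squared, b = x$b,
                 mse = x$mse, ncomp = x$ncomp, n = x$n)
}

#' Landmark-by-landmark co-heritability matrix
#'
#' For every ordered landmark pair (i, j), the 3D coordinates of offspring
#' landmark j are regressed on the 3D coordinates of father landmark i
#' (a full-rank three-predictor fit, for which the PLS regression
#' coincides with ordinary least squares) and the resulting `h2 = 2 b`
#' fills entry `(i, j)`. Heritability is a variance ratio, so entries
#' are non-negative: the local orientation of a loading field carries no
#' inheritance information, and the orientation sign used by
#' [estimate_h2()] on matched score blocks is not applied here. The
#' diagonal is the per-landmark heritability map; off-diagonal entries
#' quantify co-inheritance between facial locations. Entries are
#' mutually independent, so the computation order is immaterial.
#'
#' @param fathers,offspring n x K x 3 arrays of adjusted, symmetrized
#'   configurations with paired rows.
#' @param verbose print progress every 50 seed landmarks?
#' @return object of class `coherit_matrix`: `values` (K x K),
#'   `symmetrized = FALSE`.
#' @export
landmark_coheritability <- function(fathers, offspring, verbose = FALSE) {
  stopifnot(length(dim(fathers)) == 3L, all(dim(fathers) == dim(offspring)))
  n <- dim(fathers)[1L]; K <- dim(fathers)[2L]
  if (n < 10L) stop("need at least 10 pairs")
  Fm <- matrix(aperm(fathers, c(1L, 3L, 2L)), n, 3L * K)   # cols grouped per landmark
  Om <- matrix(aperm(offspring, c(1L, 3L, 2L)), n, 3L * K)
  Fc <- sweep(Fm, 2L, colMeans(Fm)); Oc <- sweep(Om, 2L, colMeans(Om))
  C <- crossprod(Fc, Oc)                                   # 3K x 3K
  ssy <- vapply(seq_len(K), function(j) sum(Oc[, 3L * (j - 1L) + 1:3]^2), numeric(1L))
  H <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    ii <- 3L * (i - 1L) + 1:3
    Sxx <- crossprod(Fc[, ii])
    ssx <- sum(diag(Sxx))
    # pseudoinverse: midline landmarks of the symmetric component are
    # exactly planar (x = 0), so Sxx can be rank-deficient
    e <- eigen(Sxx, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-12
    Sxx_inv <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    for (j in seq_len(K)) {
      jj <- 3L * (j - 1L) + 1:3
      Sxy <- C[ii, jj]
      expl <- sum(Sxy * (Sxx_inv %*% Sxy))   # tr(Sxy' Sxx^-1 Sxy)
      r2 <- min(max(expl / ssy[j], 0), 1)
      H[i, j] <- 2 * sqrt(r2 * ssy[j] / ssx)
    }
    if (verbose && i %% 50L == 0L)
      message("co-heritability: seed landmark ", i, "/", K)
  }
  structure(list(values = H, symmetrized = FALSE), class = "coherit_matrix")
}

#' Symmetrize a co-heritability matrix
#'
#' Replaces the matrix by `(M + t(M)) / 2` and marks it symmetrized, the
#' form required by the spectral segmentation.
#'
#' @param m a `coherit_matrix` or plain square matrix.
#' @return a symmetrized `coherit_matrix`.
#' @export
symmetrize_matrix <- function(m) {
  V <- if (inherits(m, "coherit_matrix")) m$values else as.matrix(m)
  if (nrow(V) != ncol(V)) stop("matrix must be square")
  structure(list(values = (V + t(V)) / 2, symmetrized = TRUE),
            class = "coherit_matrix")
}

#' @export
print.coherit_matrix <- function(x, ...) {
  cat("<coherit_matrix> ", nrow(x$values), " x ", ncol(x$values),
      if (x$symmetrized) " (symmetrized)", "; diagonal h2 range [",
      format(min(diag(x$values)), digits = 3), ", ",
      format(max(diag(x$values)), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Per-landmark heritability map from a co-heritability matrix
#' @param m a `coherit_matrix`.
#' @param template the matching [template_mesh()].
#' @return a [scalar_field()] of diagonal `h2` values.
#' @export
heritability_map <- function(m, template) {
  scalar_field(diag(m$values), template, name = "h2")
}
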