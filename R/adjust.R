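#' Remove covariate effects from symmetrized shapes
#'
#' Regresses vectorized shape on the covariate block (age, sex, BMI) with
#' a partial least squares fit using one component per retained covariate
#' — with a full-rank predictor block this coincides with ordinary
#' multivariate least squares — and returns the residual shapes with the
#' consensus (mean shape) added back. Fathers and offspring are adjusted
#' in separate calls, each with its own fit. Zero-variance covariates
#' (e.g. sex in a single-sex stratum) are dropped with a warning; if all
#' covariates are dropped the shapes are returned unchanged.
#'
#' @param shapes n x K x 3 array of symmetrized, aligned configurations.
#' @param covariates data frame with one row per configuration (same
#'   order) and columns `age`, `sex` ("M"/"F" or numeric), `bmi`.
#' @param cohort_tag optional label ("fathers"/"offspring") carried in the
#'   result.
#' @return object of class `adjusted_shapes`: `coords` (n x K x 3 with the
#'   mean shape restored), `covariates_used`, `cohort_tag`, `consensus`.
#' @export
adjust_covariates <- function(shapes, covariates, cohort_tag = NULL) {
  stopifnot(length(dim(shapes)) == 3L)
  n <- dim(shapes)[1L]; K <- dim(shapes)[2L]
  if (nrow(covariates) != n) stop("one covariate row per configuration required")
  Z <- cbind(age = as.numeric(covariates$age),
             sex = if (is.numeric(covariates$sex)) as.numeric(covariates$sex)
                   else as.numeric(covariates$sex == "F"),
             bmi = as.numeric(covariates$bmi))
  if (anyNA(Z)) stop("covariates must be complete")
  keep <- apply(Z, 2L, function(z) stats::var(z) > 0)
  if (any(!keep))
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(Z)[!keep], collapse = ", "))
  Z <- Z[, keep, drop = FALSE]
  Ymat <- matrix(shapes, n, 3L * K)
  consensus <- matrix(colMeans(Ymat), K, 3L)
  if (ncol(Z) == 0L) {
    warning("all covariates dropped; returning shapes unchanged")
    out <- shapes
  } else {
    fit <- plsr_fit(Z, Ymat, ncomp = ncol(Z))
    resid <- Ymat - fitted(fit)                     # removes covariate fit
    resid <- sweep(resid, 2L, colMeans(Ymat), "+")  # restore mean shape
    out <- array(resid, dim(shapes), dimnames = dimnames(shapes))
  }
  structure(list(coords = out, covariates_used = colnames(Z),
                 cohort_tag = cohort_tag, consensus = consensus),
            class = "adjusted_shapes")
}

#' @export
print.adjusted_shapes <- function(x, ...) {
  cat("<adjusted_shapes> ", dim(x$coords)[1L], " configurations",
      if (!is.null(x$cohort_tag)) paste0(" (", x$cohort_tag, ")"),
      "; adjusted for: ",
      if (length(x$covariates_used)) paste(x$covariates_used, collapse = ", ")
      else "nothing", "\n", sep = "")
  invisible(x)
}
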