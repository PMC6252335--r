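#' @importFrom stats sd
NULL

centroid_center <- function(X) sweep(X, 2L, colMeans(X))

centroid_size <- function(X) sqrt(sum(centroid_center(X)^2))

# optimal proper rotation R minimizing ||X R - Y||_F (Kabsch / orthogonal
# Procrustes with determinant correction; reflections are never produced)
kabsch_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Reflect a landmark configuration through the sagittal plane
#'
#' Negates the x-coordinate of every landmark, then relabels landmarks by
#' swapping each bilateral pair (midline landmarks keep their index), so
#' the result is again a valid configuration on the same template. The
#' operation is an involution.
#'
#' @param coords K x 3 matrix, or an n x K x 3 array (reflected per
#'   subject).
#' @param template a [template_mesh()].
#' @return object of the same shape as `coords`.
#' @export
reflect_config <- function(coords, template) {
  perm <- pair_permutation(template)
  if (length(dim(coords)) == 3L) {
    out <- coords
    out[, , 1L] <- -coords[, , 1L]
    out <- out[, perm, , drop = FALSE]
    dimnames(out) <- dimnames(coords)
    return(out)
  }
  out <- coords
  out[, 1L] <- -coords[, 1L]
  out[perm, , drop = FALSE]
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a set of configurations: each is centered,
#' optionally scaled to unit centroid size, and rotated (proper rotations
#' only) to the running consensus, which is then updated to the arithmetic
#' mean; iteration stops when the root-mean-square displacement of the
#' consensus falls below `tol`. The global rotation gauge is fixed by
#' aligning the final consensus to the first configuration, unless a
#' `symmetric_consensus` template is supplied, in which case the consensus
#' is forced to be exactly mirror-symmetric about `x = 0` at every update
#' and that symmetry fixes the gauge instead.
#'
#' @param configs n x K x 3 array (n >= 2).
#' @param remove_scale scale configurations to unit centroid size?
#' @param tol convergence tolerance on consensus RMS displacement.
#' @param max_iter iteration cap.
#' @param symmetric_consensus optional [template_mesh()]; when given, each
#'   consensus update is averaged with its own reflection.
#' @return an object of class `aligned_shapes`: `coords` (n x K x 3),
#'   `centroid_sizes`, `consensus` (K x 3), `scaling_removed`,
#'   `objective` (per-iteration sum of squared distances to consensus),
#'   `iterations`, `converged`.
#' @export
gpa <- function(configs, remove_scale = TRUE, tol = 1e-8, max_iter = 100L,
                symmetric_consensus = NULL) {
  stopifnot(length(dim(configs)) == 3L, dim(configs)[3L] == 3L)
  n <- dim(configs)[1L]; K <- dim(configs)[2L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  X <- array(0, dim(configs), dimnames = dimnames(configs))
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    ci <- centroid_center(configs[i, , ])
    sizes[i] <- sqrt(sum(ci^2))
    if (sizes[i] < .Machine$double.eps * K)
      stop("degenerate configuration (all landmarks coincident)")
    X[i, , ] <- if (remove_scale) ci / sizes[i] else ci
  }
  sym <- function(C) {
    if (is.null(symmetric_consensus)) return(C)
    (C + reflect_config(C, symmetric_consensus)) / 2
  }
  consensus <- X[1L, , ]
  if (!is.null(symmetric_consensus)) {
    # orient the initial consensus into its own mirror-symmetric pose so
    # averaging with the reflection does not flatten a rotated shape
    for (it in seq_len(50L)) {
      target <- sym(consensus)
      R0 <- kabsch_rotation(consensus, target)
      newc <- consensus %*% R0
      done <- sqrt(mean((newc - consensus)^2)) < tol
      consensus <- newc
      if (done) break
    }
    consensus <- sym(consensus)
  }
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% kabsch_rotation(X[i, , ], consensus)
    newc <- sym(colMeans(X, dims = 1L))
    objective <- c(objective, sum(sweep(X, c(2L, 3L), consensus)^2))
    delta <- sqrt(mean((newc - consensus)^2))
    consensus <- newc
    if (delta < tol) { converged <- TRUE; break }
  }
  if (is.null(symmetric_consensus)) {
    # gauge: rotate the whole set so the consensus best matches subject 1
    ref <- centroid_center(configs[1L, , ])
    if (remove_scale) ref <- ref / sizes[1L]
    R <- kabsch_rotation(consensus, ref)
    consensus <- consensus %*% R
    for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% R
  }
  structure(
    list(coords = X, centroid_sizes = sizes, consensus = consensus,
         scaling_removed = remove_scale, objective = objective,
         iterations = iter, converged = converged),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("<aligned_shapes> ", dim(x$coords)[1L], " configurations, K = ",
      dim(x$coords)[2L], "; ", x$iterations, " GPA iterations (converged: ",
      x$converged, ")\n", sep = "")
  invisible(x)
}

#' Symmetry decomposition of a set of configurations
#'
#' Runs a single GPA over the 2n-set of originals and their reflections
#' (with an exactly mirror-symmetric consensus, so alignment commutes with
#' reflection); the symmetric component of subject i is the average of the
#' aligned original and aligned reflection, the asymmetric component is
#' half their difference. The symmetric component is invariant under
#' [reflect_config()] and symmetric + asymmetric reconstructs the aligned
#' original exactly.
#'
#' @param configs n x K x 3 array of raw configurations.
#' @param template a [template_mesh()].
#' @param ... passed to [gpa()].
#' @return list with `symmetric` and `asymmetric` (n x K x 3 arrays,
#'   class `symmetry_decomposition`) and `aligned` (the 2n-set
#'   [gpa()] result; originals first, reflections after).
#' @export
symmetrize <- function(configs, template, ...) {
  n <- dim(configs)[1L]
  ids <- dimnames(configs)[[1L]]
  both <- array(0, c(2L * n, dim(configs)[2L], 3L))
  both[seq_len(n), , ] <- configs
  both[n + seq_len(n), , ] <- reflect_config(configs, template)
  dimnames(both) <- list(c(ids, if (!is.null(ids)) paste0(ids, "_refl")),
                         NULL, c("x", "y", "z"))
  aligned <- gpa(both, symmetric_consensus = template, ...)
  orig <- aligned$coords[seq_len(n), , , drop = FALSE]
  refl <- aligned$coords[n + seq_len(n), , , drop = FALSE]
  # reflect_config already relabeled the reflections, so orig and refl
  # share landmark order and can be averaged directly
  symc <- (orig + refl) / 2
  asym <- (orig - refl) / 2
  dimnames(symc) <- dimnames(asym) <- list(ids, NULL, c("x", "y", "z"))
  structure(list(symmetric = symc, asymmetric = asym, aligned = aligned),
            class = "symmetry_decomposition")
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size and
#' rotated into optimal (proper) superimposition; the distance is the
#' square root of the summed squared landmark-wise differences. Symmetric
#' in its arguments and zero exactly on the similarity-shape quotient.
#'
#' @param a,b K x 3 matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  A <- centroid_center(a); B <- centroid_center(b)
  A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
  R <- kabsch_rotation(A, B)
  sqrt(sum((A %*% R - B)^2))
}

#' Flag outlier configurations by z-scored distance to the consensus
#'
#' Each subject's score is its Procrustes distance to the GPA consensus;
#' scores are standardized to z-scores and subjects with `z >= z_max`
#' (default 2) are flagged for quality control.
#'
#' @param aligned an `aligned_shapes` object from [gpa()].
#' @param z_max flagging threshold on the z-score.
#' @return tibble with `subject`, `distance`, `z`, `flagged`.
#' @export
flag_outliers <- function(aligned, z_max = 2) {
  n <- dim(aligned$coords)[1L]
  if (n < 3L) stop("outlier flagging needs at least 3 configurations")
  d <- vapply(seq_len(n),
              function(i) procrustes_distance(aligned$coords[i, , ],
                                              aligned$consensus),
              numeric(1L))
  s <- stats::sd(d)
  z <- if (s > 0) (d - mean(d)) / s else rep(0, n)
  ids <- dimnames(aligned$coords)[[1L]]
  tibble::tibble(subject = if (is.null(ids)) as.character(seq_len(n)) else ids,
                 distance = d, z = z, flagged = z >= z_max)
}
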