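# shared fixtures (computed lazily, cached for the whole run) and
# independent oracles used by the derived-value tests

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# small default-design cohort taken through symmetrization + adjustment
demo_prepared <- function() {
  cached("demo_prepared", {
    design <- simulation_design(n_pairs = 120, grid_shape = c(5, 9), seed = 7)
    cohort <- simulate_cohort(design)
    prep <- preprocess_cohort(cohort, z_max = Inf)
    cv <- cohort$covariates
    adj_f <- suppressWarnings(adjust_covariates(
      prep$sym_fathers,
      cv[match(dimnames(prep$cohort$fathers)[[1]], cv$subject_id), ],
      "fathers"))
    adj_o <- adjust_covariates(
      prep$sym_offspring,
      cv[match(dimnames(prep$cohort$offspring)[[1]], cv$subject_id), ],
      "offspring")
    list(design = design, cohort = cohort, prep = prep,
         fathers = adj_f$coords, offspring = adj_o$coords)
  })
}

# random 3D rotation matrix (proper)
random_rotation_matrix <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# oracle: full Procrustes distance of two PLANAR (z = 0) configurations
# by exhaustive search over the in-plane rotation angle
procrustes_distance_grid_oracle <- function(a, b, n_grid = 720L) {
  ctr <- function(X) sweep(X, 2, colMeans(X))
  A <- ctr(a); A <- A / sqrt(sum(A^2))
  B <- ctr(b); B <- B / sqrt(sum(B^2))
  dist_at <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
    sqrt(sum((A %*% R - B)^2))
  }
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)
  vals <- vapply(grid, dist_at, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  stats::optimize(dist_at, c(lo, hi), tol = 1e-12)$objective
}

# oracle: minimum normalized cut over all bipartitions (m <= 12)
min_ncut_oracle <- function(S) {
  A <- pmax((S + t(S)) / 2, 0)
  diag(A) <- 0
  m <- nrow(A)
  d <- rowSums(A)
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(m - 1) - 1)) {   # element 1 always in group 0
    lab <- as.integer(intToBits(code))[seq_len(m)]
    cutw <- sum(A[lab == 0, lab == 1, drop = FALSE])
    vol0 <- sum(d[lab == 0]); vol1 <- sum(d[lab == 1])
    val <- if (cutw == 0) 0 else if (vol0 == 0 || vol1 == 0) Inf else
      cutw * (1 / vol0 + 1 / vol1)
    if (val < best_val) { best_val <- val; best <- lab }
  }
  list(labels = best, ncut = best_val)
}

# oracle: naive generalized Procrustes consensus built from pairwise
# Kabsch alignments onto the first configuration, iterated to a fixed
# point (independent of the package's gpa implementation)
gpa_consensus_oracle <- function(configs, iters = 50L) {
  n <- dim(configs)[1]
  ctr_scale <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  kabsch <- function(X, Y) {
    s <- svd(crossprod(X, Y))
    d <- sign(det(s$u %*% t(s$v)))
    s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  }
  Xs <- lapply(seq_len(n), function(i) ctr_scale(configs[i, , ]))
  ref <- Xs[[1]]
  for (it in seq_len(iters)) {
    rot <- lapply(Xs, function(X) X %*% kabsch(X, ref))
    ref <- Reduce(`+`, rot) / n
  }
  ref
}

# correlation matrix with a controllable amount of structure
random_correlation <- function(m, strength = 1) {
  Z <- matrix(stats::rnorm(m * m * 2), 2 * m, m)
  S <- crossprod(Z) / (2 * m) + strength * diag(m)
  stats::cov2cor(S)
}
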