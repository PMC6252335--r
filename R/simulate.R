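#' Design of a synthetic father-offspring shape cohort
#'
#' Describes a cohort generator with fully known heritability structure:
#' a bilaterally symmetric paraboloid template, a planted partition of its
#' landmarks into spatial modules, per-module additive genetic variance
#' `va` and environmental variance `ve` acting through smooth, mirror-
#' symmetric loading fields, linear covariate effects, iid measurement
#' noise, and nuisance rigid motion plus scale. Under the additive model
#' the father-offspring covariance of each genetic factor score is
#' `va / 2`, so the parent-offspring regression estimator is consistent
#' for the planted heritability returned by [true_heritability()].
#'
#' @param n_pairs number of father-offspring pairs (>= 3).
#' @param grid_shape template grid `(rows, cols)`; the default 11 x 22
#'   gives K = 242 landmarks.
#' @param modules data frame with one row per planted (leaf) module:
#'   columns `va`, `ve`, `n_factors`. Default: four modules with
#'   heritabilities roughly 0.8, 0.6, 0.4, 0.2 and one latent factor
#'   each.
#' @param hierarchy data frame of nested super-module factor groups:
#'   columns `members` (list-column of leaf-module label vectors), `va`,
#'   `ve`, `n_factors`. The defaults add a global factor spanning all
#'   modules plus one factor over the upper pair and one over the lower
#'   pair, so co-inheritance is structured global-to-local the way the
#'   segmentation expects; supply a zero-row tibble to disable.
#' @param planted_partition integer vector (length K, values `1..M`)
#'   assigning each landmark to a module, bilaterally symmetric; `NULL`
#'   uses the default four-quadrant partition (upper/lower face x
#'   midline-near/far).
#' @param loading_smoothness Gaussian bump bandwidth of the loading
#'   fields, in template coordinate units.
#' @param effect_scale landmark displacement (template units) per unit
#'   factor score along each unit-norm loading field. The default 0.05
#'   keeps shape deformations a few percent of face size, the scale of
#'   real facial variation.
#' @param covariate_effects named vector of displacement scales per unit
#'   covariate (age in years, sex as 0/1, BMI in kg/m^2).
#' @param noise_sd sd of iid per-coordinate measurement noise.
#' @param rigid_jitter list with `rotation_deg` (max random rotation),
#'   `translation` (max per-axis shift) and `log_scale_sd`.
#' @param seed integer seed; the cohort is bit-reproducible given the
#'   design.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_pairs = 300L,
                              grid_shape = c(11L, 22L),
                              modules = NULL,
                              hierarchy = NULL,
                              planted_partition = NULL,
                              loading_smoothness = 0.35,
                              effect_scale = 0.05,
                              covariate_effects = c(age = 0.0002, sex = 0.004,
                                                    bmi = 0.0004),
                              noise_sd = 0.002,
                              rigid_jitter = list(rotation_deg = 10,
                                                  translation = 0.5,
                                                  log_scale_sd = 0.05),
                              seed = 1L) {
  if (n_pairs < 3L) stop("n_pairs must be >= 3")
  default_mods <- is.null(modules)
  if (default_mods)
    modules <- tibble::tibble(va = c(0.8, 0.6, 0.4, 0.2),
                              ve = c(0.2, 0.4, 0.6, 0.8),
                              n_factors = 1L)
  modules <- tibble::as_tibble(modules)
  if (is.null(hierarchy)) {
    hierarchy <- if (default_mods || nrow(modules) == 4L)
      tibble::tibble(members = list(1:4, 1:2, 3:4),
                     va = c(0.5, 0.4, 0.4), ve = c(0.5, 0.6, 0.6),
                     n_factors = 1L)
    else tibble::tibble(members = list(), va = numeric(0),
                        ve = numeric(0), n_factors = integer(0))
  }
  hierarchy <- tibble::as_tibble(hierarchy)
  if (any(modules$va < 0) || any(modules$ve < 0) || noise_sd < 0 ||
      (nrow(hierarchy) && (any(hierarchy$va < 0) || any(hierarchy$ve < 0))))
    stop("variances must be non-negative")
  template <- make_template(grid_shape)
  if (is.null(planted_partition))
    planted_partition <- default_partition(template, grid_shape,
                                           nrow(modules))
  if (length(planted_partition) != template$K)
    stop("planted_partition must have one label per landmark")
  perm <- pair_permutation(template)
  if (!all(planted_partition == planted_partition[perm]))
    stop("planted_partition must be bilaterally symmetric")
  structure(
    list(n_pairs = as.integer(n_pairs), grid_shape = as.integer(grid_shape),
         K = template$K, template = template, modules = modules,
         planted_partition = as.integer(planted_partition),
         hierarchy = hierarchy,
         loading_smoothness = loading_smoothness, effect_scale = effect_scale,
         covariate_effects = covariate_effects, noise_sd = noise_sd,
         rigid_jitter = rigid_jitter, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("<simulation_design> ", x$n_pairs, " pairs, K = ", x$K, ", ",
      nrow(x$modules), " planted modules (true h2: ",
      paste(format(true_heritability(x), digits = 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# default symmetric partition: upper/lower rows x inner/outer columns
# (M = 2 or 4); labels 1..M
default_partition <- function(template, grid_shape, n_modules) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  r <- rep(seq_len(rows), each = cols)
  x <- template$vertices[, 1L]
  upper <- r <= ceiling(rows / 2)
  if (n_modules == 2L) return(ifelse(upper, 1L, 2L))
  if (n_modules != 4L)
    stop("default partition supports 2 or 4 modules; supply planted_partition")
  inner <- abs(x) <= stats::median(abs(x))
  1L + 2L * (!upper) + (!inner)
}

# orthonormal basis of the similarity-group tangent space at the template
# (3 translations, 3 infinitesimal rotations, 1 scaling), vectorized 3K
similarity_tangent_basis <- function(template) {
  V <- centroid_center(template$vertices)
  K <- nrow(V)
  z <- numeric(K); o <- rep(1, K)
  Tm <- cbind(c(o, z, z), c(z, o, z), c(z, z, o),             # translations
              c(z, -V[, 3L], V[, 2L]),                        # rotation about x
              c(V[, 3L], z, -V[, 1L]),                        # rotation about y
              c(-V[, 2L], V[, 1L], z),                        # rotation about z
              as.vector(V))                                   # scaling
  qr.Q(qr(Tm))
}

# mirror-symmetrized unit vertex normals (exactly equivariant under the
# bilateral pair map, so loading fields built on them stay symmetric)
symmetric_normals <- function(template) {
  N <- vertex_normals(template)
  perm <- pair_permutation(template)
  Nr <- N[perm, , drop = FALSE]
  Nr[, 1L] <- -Nr[, 1L]
  S <- (N + Nr) / 2
  len <- sqrt(rowSums(S^2))
  S[len > 0, ] <- S[len > 0, , drop = FALSE] / len[len > 0]
  S
}

#' Generating loading fields of a simulation design
#'
#' Gaussian bumps centered at anchors spread through each planted module,
#' mirrored across the sagittal plane, directed along (symmetrized)
#' vertex normals, projected into the Procrustes tangent space (the
#' orthocomplement of the template's translation, rotation and scaling
#' modes, so superimposition does not smear module effects across the
#' face) and orthonormalized within the module. These are the exact
#' directions along which genetic and environmental factor scores
#' displace landmarks.
#'
#' @param design a [simulation_design()].
#' @return list (one entry per module) of `n_factors` x `(3K)` matrices
#'   of orthonormal vectorized loading fields.
#' @export
module_loadings <- function(design) {
  lapply(factor_groups(design), function(g) g$loadings)[
    seq_len(nrow(design$modules))]
}

# orthonormal bump loading fields for one landmark group: factor 1 is a
# group-wide bump at the group centroid, later factors are local bumps at
# anchors spread through the group; every field is mirror-symmetric,
# supported on the group, and orthogonal to the global similarity modes
bump_fields <- function(template, members, nf, sigma2, Tb, Nrm, perm, V) {
  # one anchor per mirror orbit (a bump and its mirrored pair generate
  # the same symmetric field)
  reps <- members[members <= perm[members]]
  if (length(reps) < nf)
    stop("landmark group has fewer mirror orbits than n_factors")
  ord <- reps[order(V[reps, 2L], abs(V[reps, 1L]))]
  anchors <- ord[pmax(1L, round(seq(0.15, 0.85, length.out = nf) *
                                  length(ord)))]
  L <- matrix(0, nf, 3L * template$K)
  ctr <- colMeans(V[members, , drop = FALSE])
  diam2 <- max(rowSums(sweep(V[members, , drop = FALSE], 2L, ctr)^2))
  mask <- as.vector(matrix(seq_len(template$K) %in% members, template$K, 3L))
  Tsub <- Tb * mask
  G <- crossprod(Tb, Tsub)
  for (f in seq_len(nf)) {
    if (f == 1L) {
      # broad group-wide bump at the centroid: coverage stays nearly
      # uniform so every landmark of the group loads on the leading
      # factor, keeping within-group co-inheritance high throughout
      d2 <- rowSums(sweep(V, 2L, ctr)^2)
      g <- exp(-d2 / (8 * diam2))
    } else {
      d2 <- rowSums(sweep(V, 2L, V[anchors[f], ])^2)
      g <- exp(-d2 / (2 * sigma2))
    }
    g <- g + g[perm]                     # mirror the bump
    g[-members] <- 0                     # confine to the group
    field <- as.vector(Nrm * g)          # column-major: x block, y, z
    # subtract a correction supported on the group so the field is
    # orthogonal to every global similarity mode: displacement fields
    # with translation/rotation/scale content would otherwise be
    # smeared across the face by Procrustes superimposition
    beta <- tryCatch(solve(G, drop(crossprod(Tb, field))),
                     error = function(e) qr.solve(G, drop(crossprod(Tb, field))))
    L[f, ] <- field - drop(Tsub %*% beta)
  }
  # Gram-Schmidt within the group (linear combinations stay symmetric)
  for (f in seq_len(nf)) {
    v <- L[f, ]
    if (f > 1L) {
      prev <- L[seq_len(f - 1L), , drop = FALSE]
      v <- v - drop(crossprod(prev, prev %*% v))
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate loading field; increase module size")
    L[f, ] <- v / nv
  }
  L
}

# all generating factor groups: the leaf modules first (in label order),
# then the nested super-module groups of design$hierarchy; each entry has
# members (landmark indices), va, ve, n_factors, loadings (nf x 3K)
factor_groups <- function(design) {
  template <- design$template
  V <- template$vertices
  Nrm <- symmetric_normals(template)
  perm <- pair_permutation(template)
  sigma2 <- design$loading_smoothness^2
  Tb <- similarity_tangent_basis(template)
  groups <- list()
  for (m in seq_len(nrow(design$modules))) {
    members <- which(design$planted_partition == m)
    nf <- design$modules$n_factors[m]
    groups[[length(groups) + 1L]] <- list(
      members = members, va = design$modules$va[m],
      ve = design$modules$ve[m], n_factors = nf,
      loadings = bump_fields(template, members, nf, sigma2, Tb, Nrm, perm, V))
  }
  if (nrow(design$hierarchy) > 0L) {
    for (h in seq_len(nrow(design$hierarchy))) {
      members <- which(design$planted_partition %in%
                         design$hierarchy$members[[h]])
      nf <- design$hierarchy$n_factors[h]
      groups[[length(groups) + 1L]] <- list(
        members = members, va = design$hierarchy$va[h],
        ve = design$hierarchy$ve[h], n_factors = nf,
        loadings = bump_fields(template, members, nf, sigma2, Tb, Nrm,
                               perm, V))
    }
  }
  groups
}

# deterministic per-subject sub-seed below 2^31
subject_seed <- function(seed, counter) {
  (as.double(seed) * 7919 + counter * 104729) %% 2147483647
}

random_rotation <- function(max_deg) {
  axis <- stats::rnorm(3L); axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1L, -max_deg, max_deg) * pi / 180
  Kx <- matrix(c(0, axis[3L], -axis[2L],
                 -axis[3L], 0, axis[1L],
                 axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * Kx + (1 - cos(theta)) * (Kx %*% Kx)
}

#' Simulate a father-offspring cohort with known heritability
#'
#' For each planted module and latent factor, father genetic scores are
#' drawn `N(0, va)` and offspring scores as `g_o = g_f / 2 +
#' sqrt(3 va / 4) * xi`, giving `cov(g_f, g_o) = va / 2` and
#' `var(g_o) = va` — the one-parent additive design. Independent
#' environmental scores `N(0, ve)` are added per individual, scores
#' displace landmarks along the module's orthonormal loading fields, then
#' covariate effects (linear in age, sex, BMI), iid coordinate noise and
#' a random rigid motion plus scale per subject are applied. The result
#' is bit-reproducible given the design seed.
#'
#' @param design a [simulation_design()].
#' @return a [paired_cohort()]; the design is attached as attribute
#'   `"design"`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  template <- design$template
  n <- design$n_pairs; K <- design$K
  groups <- factor_groups(design)
  ngrp <- length(groups)

  set.seed(design$seed)
  # covariates -------------------------------------------------------------
  age_f <- round(stats::rnorm(n, 45, 5), 1)
  age_o <- round(stats::rnorm(n, 15.5, 0.6), 1)
  sex_o <- ifelse(stats::runif(n) < 0.5, "M", "F")
  bmi_f <- round(stats::rnorm(n, 26, 3), 1)
  bmi_o <- round(stats::rnorm(n, 21, 2.5), 1)
  # factor scores (per group: leaf modules, then super-module factors) -----
  gf <- go <- ef <- eo <- vector("list", ngrp)
  for (m in seq_len(ngrp)) {
    nf <- groups[[m]]$n_factors
    va <- groups[[m]]$va; ve <- groups[[m]]$ve
    gf[[m]] <- matrix(stats::rnorm(n * nf, 0, sqrt(va)), n, nf)
    go[[m]] <- gf[[m]] / 2 +
      matrix(stats::rnorm(n * nf, 0, sqrt(3 * va / 4)), n, nf)
    ef[[m]] <- matrix(stats::rnorm(n * nf, 0, sqrt(ve)), n, nf)
    eo[[m]] <- matrix(stats::rnorm(n * nf, 0, sqrt(ve)), n, nf)
  }
  # covariate fields: global symmetric bumps, unit norm ---------------------
  cov_design <- simulation_design_covariate_fields(design)

  base_vec <- as.vector(template$vertices)
  build_subject <- function(scores_g, scores_e, age, sex01, bmi, counter) {
    v <- base_vec
    for (m in seq_len(ngrp)) {
      s <- scores_g[[m]] + scores_e[[m]]
      v <- v + design$effect_scale * drop(crossprod(groups[[m]]$loadings, s))
    }
    v <- v + design$covariate_effects[["age"]] * age * cov_design[1L, ] +
      design$covariate_effects[["sex"]] * sex01 * cov_design[2L, ] +
      design$covariate_effects[["bmi"]] * bmi * cov_design[3L, ]
    X <- matrix(v, K, 3L)
    set.seed(subject_seed(design$seed, counter))
    X <- X + matrix(stats::rnorm(3L * K, 0, design$noise_sd), K, 3L)
    R <- random_rotation(design$rigid_jitter$rotation_deg)
    s <- exp(stats::rnorm(1L, 0, design$rigid_jitter$log_scale_sd))
    tr <- stats::runif(3L, -design$rigid_jitter$translation,
                       design$rigid_jitter$translation)
    sweep(s * X %*% R, 2L, tr, "+")
  }

  fid <- sprintf("F%04d", seq_len(n)); oid <- sprintf("O%04d", seq_len(n))
  fathers <- array(0, c(n, K, 3L), dimnames = list(fid, NULL, c("x", "y", "z")))
  offspring <- array(0, c(n, K, 3L), dimnames = list(oid, NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    fathers[i, , ] <- build_subject(
      lapply(gf, function(s) s[i, ]), lapply(ef, function(s) s[i, ]),
      age_f[i], 0, bmi_f[i], counter = i)
    offspring[i, , ] <- build_subject(
      lapply(go, function(s) s[i, ]), lapply(eo, function(s) s[i, ]),
      age_o[i], as.numeric(sex_o[i] == "F"), bmi_o[i], counter = n + i)
  }
  covariates <- tibble::tibble(
    subject_id = c(fid, oid),
    age = c(age_f, age_o),
    sex = c(rep("M", n), sex_o),
    bmi = c(bmi_f, bmi_o))
  cohort <- paired_cohort(fathers, offspring, covariates, template)
  attr(cohort, "design") <- design
  cohort
}

# three global unit-norm symmetric covariate fields (age, sex, bmi)
simulation_design_covariate_fields <- function(design) {
  template <- design$template
  V <- template$vertices
  Nrm <- symmetric_normals(template)
  perm <- pair_permutation(template)
  anchors <- c(which.max(V[, 2L]), which.min(V[, 2L]),
               which.min(abs(V[, 1L]) + abs(V[, 2L])))
  sigma2 <- (2 * design$loading_smoothness)^2
  Tb <- similarity_tangent_basis(template)
  out <- matrix(0, 3L, 3L * template$K)
  for (f in 1:3) {
    d2 <- rowSums(sweep(V, 2L, V[anchors[f], ])^2)
    g <- exp(-d2 / (2 * sigma2))
    g <- (g + g[perm]) / 2
    field <- as.vector(Nrm * g)
    field <- field - drop(Tb %*% crossprod(Tb, field))
    out[f, ] <- field / sqrt(sum(field^2))
  }
  out
}

#' Planted heritability of a simulation design
#'
#' Closed-form ground truth for the multivariate heritability of each
#' planted module, computed from the generating loadings. All factor
#' fields touching the module are restricted to the module's landmarks;
#' over the resulting signal subspace the population regression of
#' offspring coordinates on father coordinates gives
#' `R2 = tr(C A^-1 C) / tr(A)` with `A` the phenotypic covariance
#' (factor variances `va + ve` on the restricted loadings plus the
#' measurement-noise floor) and `C` the father-offspring cross-covariance
#' (factor terms `va / 2`), and the planted heritability is
#' `2 sqrt(R2)`. With a single isolated factor group and no noise this
#' reduces to `va / (va + ve)`.
#'
#' @param design a [simulation_design()].
#' @param module module label (1-based); `NULL` returns all modules.
#' @return numeric vector of true heritabilities.
#' @export
true_heritability <- function(design, module = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(module)) module <- seq_len(nrow(design$modules))
  if (!all(module %in% seq_len(nrow(design$modules))))
    stop("unknown module label")
  groups <- factor_groups(design)
  e2 <- design$effect_scale^2
  s2 <- design$noise_sd^2
  vapply(module, function(m) {
    idx <- which(design$planted_partition == m)
    cols <- as.vector(outer(idx, c(0L, design$K, 2L * design$K), "+"))
    Rl <- list(); va <- ve <- numeric(0)
    for (g in groups) {
      Lr <- g$loadings[, cols, drop = FALSE]
      nrm <- sqrt(rowSums(Lr^2))
      keep <- nrm > 1e-10
      if (any(keep)) {
        Rl[[length(Rl) + 1L]] <- t(Lr[keep, , drop = FALSE])
        va <- c(va, rep(g$va, sum(keep)))
        ve <- c(ve, rep(g$ve, sum(keep)))
      }
    }
    Rm <- do.call(cbind, Rl)                     # 3m x D restricted loadings
    # the per-module GPA quotients out the module's own similarity modes;
    # remove them from the restricted loadings as well
    sub <- template_mesh(design$template$vertices[idx, , drop = FALSE],
                         matrix(integer(0), 0L, 3L),
                         matrix(integer(0), 0L, 2L), seq_along(idx) - 1L)
    Qt <- similarity_tangent_basis(sub)
    Rm <- Rm - Qt %*% crossprod(Qt, Rm)
    Q <- svd(Rm)$u
    Q <- Q[, seq_len(min(ncol(Q), qr(Rm)$rank)), drop = FALSE]
    P <- crossprod(Q, Rm)                        # loadings in signal basis
    A <- e2 * P %*% (t(P) * (va + ve)) + s2 * diag(nrow(P))
    C <- e2 * P %*% (t(P) * (va / 2))
    C <- (C + t(C)) / 2
    r2 <- sum(diag(C %*% solve(A, C))) / sum(diag(A))
    2 * sqrt(r2)
  }, numeric(1L))
}
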