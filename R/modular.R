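#' Build the shape space of one co-inheritance module
#'
#' The module's landmarks are extracted from the symmetrized (and
#' covariate-adjusted) configurations of fathers and offspring, pooled,
#' and re-aligned with their own GPA so that only the module's intrinsic
#' shape is retained. The aligned coordinates are decomposed into
#' principal components and Horn's parallel analysis — comparing observed
#' eigenvalues against the 95th percentile of eigenvalues from
#' column-permuted data — selects the number of PCs that carry signal
#' above noise (always at least 1). Modules of fewer than 3 landmarks
#' skip the GPA and use centered raw coordinates.
#'
#' @param fathers,offspring n x K x 3 arrays (paired rows) of adjusted,
#'   symmetrized configurations.
#' @param landmark_ids 1-based landmark indices of the module.
#' @param module_id identifier carried into results.
#' @param pa_iters parallel-analysis permutation iterations (default 100).
#' @param seed RNG seed for the permutations.
#' @return object of class `module_space`: `scores_fathers`,
#'   `scores_offspring` (n x retained), `basis` (3m x retained),
#'   `eigenvalues`, `retained`, `consensus` (m x 3), `aligned`,
#'   `landmark_ids`, `module_id`, `n_pairs`.
#' @export
module_shape_space <- function(fathers, offspring, landmark_ids,
                               module_id = NA_integer_, pa_iters = 100L,
                               seed = 1L) {
  stopifnot(length(dim(fathers)) == 3L, all(dim(fathers) == dim(offspring)))
  n <- dim(fathers)[1L]
  m <- length(landmark_ids)
  if (m < 1L) stop("module must contain at least one landmark")
  pooled <- array(0, c(2L * n, m, 3L))
  pooled[seq_len(n), , ] <- fathers[, landmark_ids, , drop = FALSE]
  pooled[n + seq_len(n), , ] <- offspring[, landmark_ids, , drop = FALSE]
  if (m >= 3L) {
    aligned <- gpa(pooled)
    Xa <- matrix(aligned$coords, 2L * n, 3L * m)
    consensus <- aligned$consensus
  } else {
    aligned <- NULL
    Xa <- matrix(pooled, 2L * n, 3L * m)
    consensus <- matrix(colMeans(Xa), m, 3L)
  }
  mu <- colMeans(Xa)
  Xc <- sweep(Xa, 2L, mu)
  pc <- stats::prcomp(Xc, center = FALSE)
  eig <- pc$sdev^2
  retained <- parallel_analysis(Xc, eig, pa_iters = pa_iters, seed = seed)
  basis <- pc$rotation[, seq_len(retained), drop = FALSE]
  scores <- pc$x[, seq_len(retained), drop = FALSE]
  structure(
    list(scores_fathers = scores[seq_len(n), , drop = FALSE],
         scores_offspring = scores[n + seq_len(n), , drop = FALSE],
         basis = basis, center = mu, eigenvalues = eig, retained = retained,
         consensus = consensus, aligned = aligned,
         landmark_ids = landmark_ids, module_id = module_id, n_pairs = n),
    class = "module_space"
  )
}

#' @export
print.module_space <- function(x, ...) {
  cat("<module_space> module ", x$module_id, ": ", length(x$landmark_ids),
      " landmarks, ", x$retained, " retained PCs, ", x$n_pairs,
      " pairs\n", sep = "")
  invisible(x)
}

# Horn's parallel analysis: number of leading eigenvalues exceeding the
# 95th percentile of eigenvalues of column-permuted data
parallel_analysis <- function(Xc, eig, pa_iters = 100L, seed = 1L,
                              quantile = 0.95) {
  n <- nrow(Xc); p <- ncol(Xc)
  kmax <- min(n - 1L, p)
  null_eig <- matrix(0, pa_iters, kmax)
  set.seed(seed)
  for (it in seq_len(pa_iters)) {
    Xp <- apply(Xc, 2L, sample)
    sv <- svd(sweep(Xp, 2L, colMeans(Xp)), nu = 0L, nv = 0L)$d
    ev <- sv^2 / (n - 1L)
    null_eig[it, ] <- ev[seq_len(kmax)]
  }
  thresh <- apply(null_eig, 2L, stats::quantile, probs = quantile)
  keep <- which(eig[seq_len(kmax)] <= thresh)
  retained <- if (length(keep) == 0L) kmax else keep[1L] - 1L
  max(1L, retained)
}

#' Multivariate heritability of one module
#'
#' Regresses the offspring retained-PC score block on the father block
#' (all PCs jointly) with [estimate_h2()]. A subset of pairs (e.g. only
#' sons) may be selected.
#'
#' @param space a [module_shape_space()] result.
#' @param pairs indices of pairs to use (default: all).
#' @param ncomp PLS component count; `NULL` selects by cross-validation.
#' @return a `herit_estimate` with `module_id` and `n_pairs` attached.
#' @export
modular_h2 <- function(space, pairs = NULL, ncomp = NULL) {
  if (is.null(pairs)) pairs <- seq_len(space$n_pairs)
  est <- estimate_h2(space$scores_fathers[pairs, , drop = FALSE],
                     space$scores_offspring[pairs, , drop = FALSE],
                     ncomp = ncomp)
  est$module_id <- space$module_id
  est
}

#' Permutation test for modular heritability
#'
#' Father rows are re-paired uniformly at random `n_perm` times; each
#' permuted cohort's heritability is recomputed with the component count
#' of the observed fit, and the p-value uses the add-one correction
#' `p = (1 + #(h2_perm >= h2_obs)) / (1 + n_perm)`, so `p` can never be
#' smaller than `1 / (n_perm + 1)`.
#'
#' @param space a [module_shape_space()] result (or `NULL` when raw score
#'   blocks are supplied).
#' @param pairs indices of pairs to use (default: all).
#' @param n_perm number of permutations (>= 99). The add-one bound means
#'   resolving very small p-values requires raising this toward 1e6.
#' @param seed RNG seed for the permutations.
#' @param fathers,offspring optional raw score blocks overriding `space`.
#' @return list with `p_value`, `h2_obs`, `ncomp`, `n_perm`, and the
#'   observed `herit_estimate` as `estimate`.
#' @export
permutation_test <- function(space = NULL, pairs = NULL, n_perm = 9999L,
                             seed = 1L, fathers = NULL, offspring = NULL) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (is.null(fathers)) {
    if (is.null(pairs)) pairs <- seq_len(space$n_pairs)
    fathers <- space$scores_fathers[pairs, , drop = FALSE]
    offspring <- space$scores_offspring[pairs, , drop = FALSE]
  }
  X <- as.matrix(fathers); Y <- as.matrix(offspring)
  obs <- estimate_h2(X, Y)
  ncomp <- obs$ncomp
  Xc <- sweep(X, 2L, colMeans(X)); Yc <- sweep(Y, 2L, colMeans(Y))
  XtX <- crossprod(Xc)           # invariant under row permutation of Xc
  ssx <- sum(diag(XtX)); ssy <- sum(Yc^2)
  n <- nrow(Xc)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    XtY <- crossprod(Xc[pm, , drop = FALSE], Yc)
    h2p <- h2_from_crossprod(XtX, XtY, ssx, ssy, ncomp)
    if (h2p >= obs$h2) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_perm), h2_obs = obs$h2,
       ncomp = ncomp, n_perm = n_perm, estimate = obs)
}

#' Heritability of every module in a hierarchy, per offspring cohort
#'
#' The pipeline workhorse: builds a shape space for each of the
#' hierarchy's segments and estimates multivariate heritability with
#' permutation significance separately for sons and daughters.
#'
#' @param fathers,offspring n x K x 3 adjusted symmetrized arrays (paired
#'   rows).
#' @param hierarchy a [build_hierarchy()] result.
#' @param offspring_sex "M"/"F" vector, one entry per pair.
#' @param pa_iters parallel-analysis iterations per module.
#' @param n_perm permutations per test.
#' @param seed master seed; each module uses an independent sub-seed so
#'   results are reproducible in isolation.
#' @param cohorts which strata to analyze.
#' @param spaces optional prebuilt list from [build_module_spaces()]
#'   (avoids recomputing GPA and parallel analysis per call).
#' @return tibble: `module_id`, `level`, `cohort`, `n_pairs`,
#'   `n_landmarks`, `retained_pcs`, `h2`, `r_squared`, `mse`, `p_value`.
#' @export
modular_heritability <- function(fathers, offspring, hierarchy, offspring_sex,
                                 pa_iters = 100L, n_perm = 9999L, seed = 1L,
                                 cohorts = c("sons", "daughters"),
                                 spaces = NULL) {
  segs <- hierarchy$registry
  segs <- segs[order(segs$segment_id), ]
  strata <- list(sons = which(offspring_sex == "M"),
                 daughters = which(offspring_sex == "F"))[cohorts]
  if (is.null(spaces))
    spaces <- build_module_spaces(fathers, offspring, hierarchy,
                                  pa_iters = pa_iters, seed = seed)
  rows <- list()
  for (k in seq_len(nrow(segs))) {
    sid <- segs$segment_id[k]
    space <- spaces[[as.character(sid)]]
    if (is.null(space)) next
    idx <- space$landmark_ids
    for (cname in names(strata)) {
      pairs <- strata[[cname]]
      if (length(pairs) < 10L) next
      pt <- permutation_test(space, pairs = pairs, n_perm = n_perm,
                             seed = seed + 1000L * sid +
                               match(cname, names(strata)))
      est <- pt$estimate
      rows[[length(rows) + 1L]] <- tibble::tibble(
        module_id = sid, level = segs$level[k], cohort = cname,
        n_pairs = length(pairs), n_landmarks = length(idx),
        retained_pcs = space$retained, h2 = est$h2,
        r_squared = est$r_squared, mse = est$mse, p_value = pt$p_value)
    }
  }
  dplyr::bind_rows(rows)
}

#' Build shape spaces for every segment of a hierarchy
#'
#' @param fathers,offspring n x K x 3 adjusted symmetrized arrays.
#' @param hierarchy a [build_hierarchy()] result.
#' @param pa_iters parallel-analysis iterations per module.
#' @param seed master seed; module with id `s` uses `seed + s`.
#' @return named list of [module_shape_space()] results, keyed by segment
#'   id; empty segments are omitted.
#' @export
build_module_spaces <- function(fathers, offspring, hierarchy,
                                pa_iters = 100L, seed = 1L) {
  ids <- sort(hierarchy$registry$segment_id)
  out <- list()
  for (sid in ids) {
    idx <- hierarchy$members[[as.character(sid)]]
    if (is.null(idx) || length(idx) == 0L) next
    out[[as.character(sid)]] <-
      module_shape_space(fathers, offspring, idx, module_id = sid,
                         pa_iters = pa_iters, seed = seed + sid)
  }
  out
}

#' RV correlations between module score blocks
#'
#' Entry (a, b) is the RV coefficient — a matrix correlation in `[0, 1]`,
#' invariant to rotation of either block — between the retained-PC score
#' blocks of modules a and b, computed on the pooled fathers + offspring
#' scores by default. This is the inter-module dependency matrix used
#' for the effective-number-of-tests correction and for modular
#' co-heritability summaries.
#'
#' @param spaces list of [module_shape_space()] results on the same
#'   subjects.
#' @param use which score block to correlate: pooled (default), fathers
#'   only, or offspring only.
#' @return M x M symmetric matrix with unit diagonal.
#' @export
module_correlations <- function(spaces, use = c("pooled", "fathers",
                                                "offspring")) {
  use <- match.arg(use)
  blocks <- lapply(spaces, function(sp) {
    B <- switch(use,
                pooled = rbind(sp$scores_fathers, sp$scores_offspring),
                fathers = sp$scores_fathers,
                offspring = sp$scores_offspring)
    sweep(B, 2L, colMeans(B))
  })
  M <- length(blocks)
  self <- vapply(blocks, function(Xc) sum(crossprod(Xc)^2), numeric(1L))
  out <- diag(1, M)
  for (a in seq_len(M - 1L)) {
    for (b in (a + 1L):M) {
      num <- sum(crossprod(blocks[[a]], blocks[[b]])^2)
      out[a, b] <- out[b, a] <- num / sqrt(self[a] * self[b])
    }
  }
  dimnames(out) <- list(names(spaces), names(spaces))
  out
}

#' Effective number of independent tests (Li-Ji correction)
#'
#' From the eigenvalues of the inter-module correlation matrix:
#' `m_eff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`. The
#' family-wise threshold is `alpha_adj = fwer / round(m_eff)`, the
#' integer-division reporting convention.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param fwer family-wise error rate (default 0.05).
#' @return object of class `multiple_testing`: `m_eff`, `alpha_adj`,
#'   `eigenvalues`, `fwer`, `n_tests`.
#' @export
effective_tests <- function(corr, fwer = 0.05) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  lambda <- pmax(eigen((corr + t(corr)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values, 0)
  m_eff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  m_eff <- min(max(m_eff, 1), nrow(corr))  # guard float round-off at the edges
  structure(
    list(m_eff = m_eff, alpha_adj = fwer / round(m_eff),
         eigenvalues = lambda, fwer = fwer, n_tests = nrow(corr)),
    class = "multiple_testing"
  )
}

#' @export
print.multiple_testing <- function(x, ...) {
  cat("<multiple_testing> ", x$n_tests, " tests, m_eff = ",
      format(x$m_eff, digits = 4), ", adjusted alpha = ",
      format(x$alpha_adj, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Latent-variable morphs and normal displacement map
#'
#' For one latent pair of a fitted offspring-on-father PLS model in a
#' module shape space, constructs the shapes at plus and minus
#' `sd_multiplier` standard deviations of the latent score along the
#' response-side shape direction, and the per-landmark displacement
#' projected on the template vertex normal (rotated into the module
#' frame) — the map used to visualize a heritable shape-change direction.
#'
#' @param space a [module_shape_space()] result.
#' @param model a `plsr_model` fitted on the module's score blocks.
#' @param component latent pair index.
#' @param sd_multiplier morph amplitude in latent-score SDs (default 4).
#' @param template the full-face [template_mesh()] (for normals and for
#'   embedding the map as a [scalar_field()]).
#' @return list: `morph_plus`, `morph_minus` (m x 3), `displacement`
#'   (m x 3, plus minus consensus), `normal_displacement` (length m),
#'   `field` (full-K [scalar_field()], zero outside the module),
#'   `component`, `score_sd`.
#' @export
latent_morphs <- function(space, model, component = 1L, sd_multiplier = 4,
                          template = NULL) {
  if (component < 1L || component > model$ncomp)
    stop("component out of range")
  m <- length(space$landmark_ids)
  tt <- model$Ts[, component]
  score_sd <- stats::sd(tt)
  dir_scores <- model$C[, component]                  # offspring-PC direction
  dir_shape <- drop(space$basis %*% dir_scores)       # 3m shape direction
  disp <- sd_multiplier * score_sd * matrix(dir_shape, m, 3L)
  consensus <- space$consensus
  morph_plus <- consensus + disp
  morph_minus <- consensus - disp
  out <- list(morph_plus = morph_plus, morph_minus = morph_minus,
              displacement = disp, component = component,
              score_sd = score_sd)
  if (!is.null(template)) {
    Nrm <- vertex_normals(template)[space$landmark_ids, , drop = FALSE]
    Vt <- template$vertices[space$landmark_ids, , drop = FALSE]
    R <- kabsch_rotation(centroid_center(Vt), centroid_center(consensus))
    nd <- rowSums(disp * (Nrm %*% R))
    vals <- numeric(template$K)
    vals[space$landmark_ids] <- nd
    out$normal_displacement <- nd
    out$field <- scalar_field(vals, template, name = "normal_displacement")
  }
  out
}

#' Heritability stability under subsampling
#'
#' Recomputes the modular heritability on random subsamples of
#' increasing size; the spread of estimates across replicates narrows as
#' the subsample grows, showing where the estimate stabilizes. Sampled
#' indices are sorted, so a subsample of the full size reproduces the
#' full-sample estimate exactly.
#'
#' @param space a [module_shape_space()] result.
#' @param sizes subsample sizes (each <= n).
#' @param reps replicates per size.
#' @param seed RNG seed.
#' @param pairs optional pair subset defining the cohort.
#' @return tibble: `size`, `rep`, `h2`; summarize with
#'   [summarize_stability()].
#' @export
subsample_stability <- function(space, sizes, reps = 10L, seed = 1L,
                                pairs = NULL) {
  if (is.null(pairs)) pairs <- seq_len(space$n_pairs)
  n <- length(pairs)
  if (max(sizes) > n) stop("subsample size exceeds available pairs")
  X <- space$scores_fathers[pairs, , drop = FALSE]
  Y <- space$scores_offspring[pairs, , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (s in sizes) {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, s))
      est <- estimate_h2(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(size = s, rep = r,
                                                  h2 = est$h2)
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarize a stability curve
#' @param curve tibble from [subsample_stability()].
#' @return tibble with per-size mean and standard deviation of `h2`.
#' @export
summarize_stability <- function(curve) {
  dplyr::summarise(dplyr::group_by(curve, .data$size),
                   mean_h2 = mean(.data$h2),
                   sd_h2 = stats::sd(.data$h2), .groups = "drop")
}
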