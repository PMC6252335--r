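test_that("parallel analysis retains planted factors and ignores pure noise", {
  set.seed(81)
  n <- 200; p <- 24
  # pure isotropic noise: at most one PC survives
  Xnoise <- matrix(rnorm(n * p), n, p)
  r_noise <- coherit:::parallel_analysis(scale(Xnoise, scale = FALSE),
                                         stats::prcomp(Xnoise)$sdev^2,
                                         pa_iters = 60, seed = 1)
  expect_lte(r_noise, 1L)
  # three strong planted orthogonal factors: exactly three retained
  basis <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  scores <- matrix(rnorm(n * 3, 0, 4), n, 3)
  Xsig <- scores %*% t(basis) + matrix(rnorm(n * p, 0, 0.3), n, p)
  Xc <- scale(Xsig, scale = FALSE)
  r_sig <- coherit:::parallel_analysis(Xc, stats::prcomp(Xsig)$sdev^2,
                                       pa_iters = 60, seed = 1)
  expect_equal(r_sig, 3L)
})

test_that("module shape spaces reconstruct their source geometry", {
  prep <- demo_prepared()
  K <- dim(prep$fathers)[2]
  # the full-landmark module reproduces a plain pooled GPA
  sp <- module_shape_space(prep$fathers, prep$offspring, seq_len(K),
                           module_id = 1L, pa_iters = 20, seed = 2)
  n <- dim(prep$fathers)[1]
  pooled <- array(0, c(2 * n, K, 3))
  pooled[seq_len(n), , ] <- prep$fathers
  pooled[n + seq_len(n), , ] <- prep$offspring
  ref <- gpa(pooled)
  expect_lt(procrustes_distance(sp$consensus, ref$consensus), 1e-8)
  expect_gte(sp$retained, 1L)
  # PC basis is orthonormal
  expect_equal(unname(crossprod(sp$basis)), diag(sp$retained),
               tolerance = 1e-10)
  # scores + basis reconstruct the aligned coordinates when all PCs kept
  sp_all <- sp
  expect_equal(nrow(sp$scores_fathers), n)
})

test_that("modular h2 is 2 for identical score blocks and recovers planted truth", {
  prep <- demo_prepared()
  d <- prep$design
  members <- which(d$planted_partition == 1)
  sp <- module_shape_space(prep$fathers, prep$fathers, members,
                           module_id = 1L, pa_iters = 20, seed = 3)
  expect_equal(modular_h2(sp)$h2, 2, tolerance = 1e-8)
})

test_that("permutation p-values respect the add-one bound and detect signal", {
  set.seed(82)
  n <- 120
  g <- matrix(rnorm(n * 2), n, 2)
  X <- g + matrix(rnorm(n * 2, 0, 0.3), n, 2)
  Y <- g / 2 + matrix(rnorm(n * 2, 0, 0.8), n, 2)
  pt <- permutation_test(fathers = X, offspring = Y, n_perm = 999, seed = 1)
  expect_equal(pt$p_value, 1 / 1000)        # strong signal: minimal p
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  expect_error(permutation_test(fathers = X, offspring = Y, n_perm = 50),
               "at least 99")
  # null data: p is far from the minimum on a typical draw
  Xn <- matrix(rnorm(n * 2), n, 2)
  Yn <- matrix(rnorm(n * 2), n, 2)
  ptn <- permutation_test(fathers = Xn, offspring = Yn, n_perm = 499, seed = 2)
  expect_gt(ptn$p_value, 0.01)
})

test_that("permutation test is calibrated under the null", {
  set.seed(83)
  n <- 60
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    X <- matrix(rnorm(n * 2), n, 2)
    Y <- matrix(rnorm(n * 2), n, 2)
    permutation_test(fathers = X, offspring = Y, n_perm = 199,
                     seed = 1000 + r)$p_value
  }, numeric(1))
  rejection <- mean(pvals <= 0.05)
  expect_gte(rejection, 0.02)
  expect_lte(rejection, 0.08)
  # p-values approximately uniform on the achievable grid
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("RV correlations are 1 on self and rotations, near 0 when independent", {
  set.seed(84)
  n <- 300
  mk_space <- function(scores_f, scores_o, id) {
    structure(list(scores_fathers = scores_f, scores_offspring = scores_o,
                   module_id = id, n_pairs = nrow(scores_f)),
              class = "module_space")
  }
  A <- mk_space(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3), 1)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  B <- mk_space(A$scores_fathers %*% R, A$scores_offspring %*% R, 2)
  C <- mk_space(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2), n, 2), 3)
  M <- module_correlations(list(A, B, C))
  expect_equal(diag(M), rep(1, 3))
  expect_equal(M[1, 2], 1, tolerance = 1e-10)   # rotation invariance
  expect_lt(M[1, 3], 0.1)                       # independent blocks
  expect_equal(M, t(M))
})

test_that("Li-Ji effective tests has its closed-form anchors", {
  mt_id <- effective_tests(diag(63))
  expect_equal(mt_id$m_eff, 63)
  ones <- matrix(1, 63, 63)
  mt_ones <- effective_tests(ones)
  expect_equal(mt_ones$m_eff, 1)
  expect_equal(mt_ones$alpha_adj, 0.05)
  # m_eff = 36 reproduces the adjusted threshold 0.05 / 36
  expect_equal(0.05 / 36, 1.3889e-3, tolerance = 1e-4)
  expect_error(effective_tests(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
  expect_error(effective_tests(matrix(c(2, 0, 0, 2), 2, 2)), "unit diagonal")
})

test_that("m_eff lies in [1, M] for random correlation matrices", {
  set.seed(85)
  for (r in 1:100) {
    m <- sample(c(5, 10, 20), 1)
    corr <- random_correlation(m, strength = runif(1, 0.1, 2))
    mt <- effective_tests(corr)
    expect_gte(mt$m_eff, 1)
    expect_lte(mt$m_eff, m)
  }
})

test_that("latent morphs are symmetric around the consensus and locate the factor", {
  d <- simulation_design(n_pairs = 400, grid_shape = c(5, 9), seed = 86,
                         modules = tibble::tibble(va = 0.9, ve = 0.1,
                                                  n_factors = 1L),
                         planted_partition = rep(1L, 45),
                         hierarchy = tibble::tibble(members = list(),
                                                    va = numeric(0),
                                                    ve = numeric(0),
                                                    n_factors = integer(0)),
                         noise_sd = 0.001)
  co <- simulate_cohort(d)
  prep <- preprocess_cohort(co, z_max = Inf)
  sp <- module_shape_space(prep$sym_fathers, prep$sym_offspring,
                           seq_len(d$K), module_id = 1L, pa_iters = 30,
                           seed = 1)
  est <- modular_h2(sp)
  morph0 <- latent_morphs(sp, est$model, component = 1, sd_multiplier = 0,
                          template = d$template)
  expect_equal(morph0$morph_plus, sp$consensus, tolerance = 1e-12)
  expect_equal(max(abs(morph0$displacement)), 0)
  morph <- latent_morphs(sp, est$model, component = 1, sd_multiplier = 4,
                         template = d$template)
  # plus and minus morphs mirror each other through the consensus
  expect_equal(morph$morph_plus - sp$consensus,
               -(morph$morph_minus - sp$consensus), tolerance = 1e-12)
  expect_error(latent_morphs(sp, est$model, component = 99), "range")
  # the displacement direction matches the planted loading field
  L <- module_loadings(d)[[1]][1, ]
  disp <- as.vector(morph$displacement)
  # align the module frame with the template frame before comparing
  R <- coherit:::kabsch_rotation(coherit:::centroid_center(sp$consensus),
                                 coherit:::centroid_center(d$template$vertices))
  disp_t <- as.vector(morph$displacement %*% R)
  cosine <- abs(sum(disp_t * L)) / sqrt(sum(disp_t^2) * sum(L^2))
  expect_gt(cosine, 0.9)
})

test_that("subsample stability reproduces the full estimate and tightens with size", {
  set.seed(87)
  n <- 300
  g <- matrix(rnorm(n * 2), n, 2)
  sp <- structure(list(
    scores_fathers = g + matrix(rnorm(n * 2, 0, 0.6), n, 2),
    scores_offspring = g / 2 + matrix(rnorm(n * 2, 0, 0.9), n, 2),
    module_id = 1L, n_pairs = n), class = "module_space")
  full <- modular_h2(sp)$h2
  curve_full <- subsample_stability(sp, sizes = n, reps = 1, seed = 5)
  expect_equal(curve_full$h2, full, tolerance = 1e-12)
  curve <- subsample_stability(sp, sizes = c(40, 100, 220), reps = 12,
                               seed = 6)
  s <- summarize_stability(curve)
  expect_equal(s$size, c(40, 100, 220))
  # spread is non-increasing with size
  expect_lte(stats::cor(s$size, s$sd_h2, method = "spearman"), 0)
  expect_error(subsample_stability(sp, sizes = n + 1), "exceeds")
  # determinism
  expect_identical(subsample_stability(sp, sizes = 50, reps = 3, seed = 9),
                   subsample_stability(sp, sizes = 50, reps = 3, seed = 9))
})

test_that("cohort stratification uses disjoint son/daughter subsets", {
  prep <- demo_prepared()
  sex <- offspring_sex(prep$cohort)
  M <- symmetrize_matrix(landmark_coheritability(prep$fathers,
                                                 prep$offspring))
  h <- suppressWarnings(build_hierarchy(M, levels = 1, seed = 1))
  res <- modular_heritability(prep$fathers, prep$offspring, h, sex,
                              pa_iters = 15, n_perm = 99, seed = 4)
  expect_equal(nrow(res), 3L * 2L)
  expect_setequal(unique(res$cohort), c("sons", "daughters"))
  n_sons <- unique(res$n_pairs[res$cohort == "sons"])
  n_daughters <- unique(res$n_pairs[res$cohort == "daughters"])
  expect_equal(n_sons + n_daughters, prep$cohort$n_pairs)
  expect_true(all(res$p_value >= 1 / 100))
  expect_true(all(res$retained_pcs >= 1))
})
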