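test_that("shape R-squared has its closed-form limits", {
  set.seed(61)
  Y <- matrix(rnorm(60), 20, 3)
  expect_equal(shape_r2(Y, Y), 1)
  Ybar <- matrix(colMeans(Y), 20, 3, byrow = TRUE)
  expect_equal(shape_r2(Y, Ybar), 0)
  expect_error(shape_r2(Ybar, Ybar), "zero total variance")
  # univariate case equals classical OLS R-squared
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.7)
  ols <- stats::lm(y ~ x)
  expect_equal(shape_r2(cbind(y), cbind(stats::fitted(ols))),
               summary(ols)$r.squared, tolerance = 1e-12)
  expect_warning(r <- shape_r2(cbind(y), cbind(y + 10 * sd(y))), "clipped")
  expect_equal(r, 0)
})

test_that("the R2-to-coefficient transform matches the univariate identity", {
  expect_equal(r2_to_b(1, 2, 2), 1)
  expect_equal(r2_to_b(0, 1, 5), 0)
  expect_error(r2_to_b(0.5, 0, 1), "positive")
  set.seed(62)
  x <- rnorm(200); y <- -0.6 * x + rnorm(200, 0, 0.4)
  ols <- stats::lm(y ~ x)
  r2 <- summary(ols)$r.squared
  b <- r2_to_b(r2, sum((x - mean(x))^2), sum((y - mean(y))^2))
  expect_equal(b, abs(unname(coef(ols)[2])), tolerance = 1e-6)
})

test_that("estimate_h2 reproduces the OLS slope in the univariate collapse", {
  set.seed(63)
  x <- matrix(rnorm(100), 100, 1)
  y <- 0.45 * x + matrix(rnorm(100, 0, 0.8), 100, 1)
  est <- estimate_h2(x, y, ncomp = 1)
  slope <- unname(coef(stats::lm(y ~ x))[2])
  expect_equal(est$b, slope, tolerance = 1e-6)
  expect_equal(est$h2, 2 * est$b)
  # negative slope carries through with its sign
  y2 <- -0.45 * x + matrix(rnorm(100, 0, 0.8), 100, 1)
  est2 <- estimate_h2(x, y2, ncomp = 1)
  expect_equal(est2$b, unname(coef(stats::lm(y2 ~ x))[2]), tolerance = 1e-6)
})

test_that("self-regression gives b = 1 and h2 = 2 reported raw", {
  set.seed(64)
  X <- matrix(rnorm(150), 50, 3)
  est <- estimate_h2(X, X, ncomp = 3)
  expect_equal(est$b, 1, tolerance = 1e-10)
  expect_equal(est$h2, 2, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-10)
})

test_that("broken pairing centers the estimate at zero", {
  set.seed(65)
  n <- 800
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- 0.3 * X + matrix(rnorm(n * 3), n, 3)
  h2s <- vapply(1:50, function(i) estimate_h2(X[sample(n), ], Y)$h2,
                numeric(1))
  expect_lt(abs(mean(h2s)), 0.05)
})

test_that("h2 recovery on simulated scores across the heritability range", {
  set.seed(66)
  for (h2_true in c(0.2, 0.5, 0.8)) {
    ests <- vapply(1:8, function(r) {
      n <- 800
      g_f <- matrix(rnorm(n * 2), n, 2)
      g_o <- g_f / 2 + matrix(rnorm(n * 2, 0, sqrt(3 / 4)), n, 2)
      s_e <- sqrt(1 / h2_true - 1)
      X <- g_f + matrix(rnorm(n * 2, 0, s_e), n, 2)
      Y <- g_o + matrix(rnorm(n * 2, 0, s_e), n, 2)
      estimate_h2(X, Y)$h2
    }, numeric(1))
    expect_lt(abs(mean(ests) - h2_true), 0.08)
  }
})

test_that("the co-heritability matrix equals looped estimate_h2 calls", {
  prep <- demo_prepared()
  ids <- c(3, 11, 19, 27, 40)  # five landmarks, mixed modules + midline
  f <- prep$fathers[, ids, , drop = FALSE]
  o <- prep$offspring[, ids, , drop = FALSE]
  M <- landmark_coheritability(f, o)
  expect_false(M$symmetrized)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      est <- suppressWarnings(estimate_h2(f[, i, ], o[, j, ], ncomp = 3))
      # the matrix stores the magnitude; estimate_h2 additionally carries
      # the orientation sign of the cross-covariance trace
      expect_equal(M$values[i, j], abs(est$h2), tolerance = 1e-8)
    }
  }
})

test_that("self-paired cohorts give a diagonal of exactly 2", {
  prep <- demo_prepared()
  M <- landmark_coheritability(prep$fathers, prep$fathers)
  expect_equal(unname(diag(M$values)), rep(2, dim(prep$fathers)[2]),
               tolerance = 1e-8)
})

test_that("planted independent modules show block-structured co-heritability", {
  d <- simulation_design(n_pairs = 500, grid_shape = c(4, 6), seed = 67,
                         modules = tibble::tibble(va = c(0.8, 0.8),
                                                  ve = c(0.2, 0.2),
                                                  n_factors = 1L),
                         hierarchy = tibble::tibble(members = list(),
                                                    va = numeric(0),
                                                    ve = numeric(0),
                                                    n_factors = integer(0)))
  co <- simulate_cohort(d)
  prep <- preprocess_cohort(co, z_max = Inf)
  M <- symmetrize_matrix(landmark_coheritability(prep$sym_fathers,
                                                 prep$sym_offspring))$values
  p <- d$planted_partition
  within <- mean(c(M[p == 1, p == 1], M[p == 2, p == 2]))
  between <- mean(M[p == 1, p == 2])
  expect_gt(within, between + 0.2)
  expect_lt(abs(between), 0.25)  # near the finite-sample floor
})

test_that("matrix symmetrization is the symmetric average", {
  M <- matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE)
  S <- symmetrize_matrix(M)
  expect_true(S$symmetrized)
  expect_equal(S$values, matrix(c(0, 2, 2, 0), 2, 2))
  expect_identical(S$values, t(S$values))
  sym_in <- diag(3)
  expect_equal(symmetrize_matrix(sym_in)$values, sym_in)
  expect_error(symmetrize_matrix(matrix(0, 2, 3)), "square")
})

test_that("the estimator is invariant to a common rigid motion of the inputs", {
  d <- simulation_design(n_pairs = 120, grid_shape = c(4, 5), seed = 68,
                         modules = tibble::tibble(va = 0.6, ve = 0.4,
                                                  n_factors = 1L),
                         planted_partition = rep(1L, 20),
                         hierarchy = tibble::tibble(members = list(),
                                                    va = numeric(0),
                                                    ve = numeric(0),
                                                    n_factors = integer(0)))
  co <- simulate_cohort(d)
  est_from <- function(fa, of) {
    prep <- preprocess_cohort(
      paired_cohort(fa, of, co$covariates, d$template), z_max = Inf)
    sp <- module_shape_space(prep$sym_fathers, prep$sym_offspring,
                             seq_len(d$K), pa_iters = 20, seed = 1)
    modular_h2(sp)$h2
  }
  base_h2 <- est_from(co$fathers, co$offspring)
  set.seed(99)
  R <- random_rotation_matrix()
  move <- function(arr) {
    out <- arr
    for (i in seq_len(dim(arr)[1]))
      out[i, , ] <- sweep(1.3 * arr[i, , ] %*% R, 2, c(10, -4, 2), "+")
    out
  }
  moved_h2 <- est_from(move(co$fathers), move(co$offspring))
  expect_equal(moved_h2, base_h2, tolerance = 1e-6)
})
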