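test_that("same seed gives a bit-identical cohort", {
  d <- simulation_design(n_pairs = 10, grid_shape = c(4, 5), seed = 31)
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a$fathers, b$fathers)
  expect_identical(a$offspring, b$offspring)
  expect_identical(a$covariates, b$covariates)
  # different seed changes the data
  d2 <- simulation_design(n_pairs = 10, grid_shape = c(4, 5), seed = 32)
  expect_false(identical(simulate_cohort(d2)$fathers, a$fathers))
})

test_that("planted partitions must be symmetric and labels valid", {
  tm <- make_template(c(4, 6))
  bad <- rep(1L, tm$K); bad[1] <- 2L  # breaks mirror symmetry
  expect_error(simulation_design(n_pairs = 5, grid_shape = c(4, 6),
                                 modules = tibble::tibble(va = c(1, 1),
                                                          ve = c(0, 0),
                                                          n_factors = 1L),
                                 planted_partition = bad),
               "symmetric")
  expect_error(simulation_design(n_pairs = 5, noise_sd = -1), "non-negative")
})

test_that("generating loadings are orthonormal, symmetric, module-confined", {
  d <- simulation_design(n_pairs = 10, grid_shape = c(6, 9), seed = 33,
                         modules = tibble::tibble(va = c(0.5, 0.5),
                                                  ve = c(0.5, 0.5),
                                                  n_factors = 3L),
                         hierarchy = tibble::tibble(members = list(),
                                                    va = numeric(0),
                                                    ve = numeric(0),
                                                    n_factors = integer(0)))
  L <- module_loadings(d)
  perm <- coherit:::pair_permutation(d$template)
  for (m in 1:2) {
    G <- tcrossprod(L[[m]])
    expect_equal(G, diag(3), tolerance = 1e-10)
    members <- which(d$planted_partition == m)
    for (f in 1:3) {
      field <- matrix(L[[m]][f, ], d$K, 3)
      # confined to the module
      expect_equal(sum(abs(field[-members, ])), 0)
      # mirror-equivariant: x flips, partner landmarks swap
      mirrored <- field[perm, ]
      mirrored[, 1] <- -mirrored[, 1]
      expect_equal(mirrored, field, tolerance = 1e-10)
      # orthogonal to every global similarity mode
      Tb <- coherit:::similarity_tangent_basis(d$template)
      expect_lt(max(abs(crossprod(Tb, as.vector(field)))), 1e-8)
    }
  }
})

test_that("father-offspring factor scores covary at va / 2", {
  # project deviations from the template onto a generating loading field;
  # with no noise, jitter or covariate effects the projection recovers
  # the factor score exactly
  d <- simulation_design(
    n_pairs = 2000, grid_shape = c(4, 5), seed = 34,
    modules = tibble::tibble(va = 0.8, ve = 0.2, n_factors = 1L),
    planted_partition = rep(1L, 20),
    hierarchy = tibble::tibble(members = list(), va = numeric(0),
                               ve = numeric(0), n_factors = integer(0)),
    covariate_effects = c(age = 0, sex = 0, bmi = 0), noise_sd = 0,
    rigid_jitter = list(rotation_deg = 0, translation = 0, log_scale_sd = 0))
  co <- simulate_cohort(d)
  L <- module_loadings(d)[[1]][1, ]
  base <- as.vector(d$template$vertices)
  sf <- apply(co$fathers, 1, function(X) sum((as.vector(X) - base) * L)) /
    d$effect_scale
  so <- apply(co$offspring, 1, function(X) sum((as.vector(X) - base) * L)) /
    d$effect_scale
  # projections are g + e; environmental parts are independent, so
  # cov(score_f, score_o) estimates va / 2 = 0.4 (SE ~ 0.023 at n = 2000)
  expect_equal(stats::cov(sf, so), 0.4, tolerance = 0.1)
  expect_equal(stats::var(sf), 1.0, tolerance = 0.15)  # va + ve
})

test_that("cohorts are bilaterally symmetric in expectation", {
  d <- simulation_design(n_pairs = 150, grid_shape = c(4, 7), seed = 35,
                         modules = tibble::tibble(va = c(0.5, 0.5),
                                                  ve = c(0.5, 0.5),
                                                  n_factors = 1L))
  co <- simulate_cohort(d)
  dec <- symmetrize(co$fathers, d$template)
  # asymmetric component comes only from iid noise: subject-wise means
  # shrink at the 1 / sqrt(n) rate and the population mean is ~0
  mean_asym <- apply(dec$asymmetric, c(2, 3), mean)
  expect_lt(max(abs(mean_asym)), 5 * d$noise_sd / sqrt(150))
})

test_that("true heritability has the expected closed forms", {
  iso <- function(va, ve, noise = 0) {
    simulation_design(
      n_pairs = 5, grid_shape = c(4, 5), seed = 1,
      modules = tibble::tibble(va = va, ve = ve, n_factors = 1L),
      planted_partition = rep(1L, 20),
      hierarchy = tibble::tibble(members = list(), va = numeric(0),
                                 ve = numeric(0), n_factors = integer(0)),
      noise_sd = noise)
  }
  expect_equal(true_heritability(iso(1, 0)), 1.0, tolerance = 1e-8)
  expect_equal(true_heritability(iso(0, 1)), 0.0, tolerance = 1e-8)
  expect_equal(true_heritability(iso(0.6, 0.4)), 0.6, tolerance = 1e-8)
  # noise enters as (noise_sd / effect_scale)^2 per factor direction
  d <- iso(0.6, 0.4, noise = 0.05)
  expect_equal(true_heritability(d), 0.6 / (1 + (0.05 / d$effect_scale)^2),
               tolerance = 1e-6)
  expect_error(true_heritability(d, module = 9), "unknown")
})

test_that("no-signal and pure-signal designs bracket the estimator", {
  base <- function(va, ve, seed) {
    simulation_design(
      n_pairs = 400, grid_shape = c(4, 5), seed = seed,
      modules = tibble::tibble(va = va, ve = ve, n_factors = 1L),
      planted_partition = rep(1L, 20),
      hierarchy = tibble::tibble(members = list(), va = numeric(0),
                                 ve = numeric(0), n_factors = integer(0)),
      noise_sd = 0.001)
  }
  est_for <- function(d) {
    co <- simulate_cohort(d)
    prep <- preprocess_cohort(co, z_max = Inf)
    sp <- module_shape_space(prep$sym_fathers, prep$sym_offspring,
                             seq_len(d$K), pa_iters = 30, seed = 1)
    modular_h2(sp)$h2
  }
  # va = 0: no genetic signal, estimate near 0
  h0 <- mean(vapply(1:3, function(s) est_for(base(0, 1, 40 + s)), numeric(1)))
  expect_lt(abs(h0), 0.15)
  # ve = 0, no noise: fully additive limit, estimate near 1
  h1 <- est_for(base(1, 1e-6, 44))
  expect_equal(h1, 1, tolerance = 0.12)
})
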