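# Residuals, the EAR decomposition, the cell standard-error formula, ESE,
# and misfit statistics.

test_that("residuals are X - E on observed cells only", {
  X <- matrix(c(1, NA, 3, 4), 2, 2)
  E <- matrix(0.25, 2, 2)
  res <- residual_matrix(X, E)
  expect_equal(res[1, 1], 0.75)
  expect_true(is.na(res[2, 1]))
  expect_equal(residual_matrix(E, E), matrix(0, 2, 2))
})

test_that("residual columns satisfy the least-squares normal equations", {
  spec <- simulation_spec(n_persons = 200, n_items = 50, true_d = 3,
                          noise_base = 1, missing_fraction = 0,
                          missing_pattern = "random", seed = 41)
  sim <- simulate_dataset(spec)
  fit <- als_decompose(sim$X$values, 3, tol = 1e-9, max_iter = 100)
  res <- residual_matrix(sim$X, fitted(fit))
  # each residual column is orthogonal to the person-coordinate basis the
  # column solve used, and column means are correspondingly small
  expect_lt(max(abs(crossprod(fit$R, res))), 1e-5)
  expect_lt(max(abs(colMeans(res))), 0.3)
})

test_that("EAR recovers a homoscedastic residual scale", {
  set.seed(31)
  res <- matrix(rnorm(300 * 80, sd = 0.5), 300, 80)
  ear <- estimate_ear(res, seed = 1)$ear
  expect_gt(median(ear), 0.4)
  expect_lt(median(ear), 0.6)
})

test_that("EAR separates rows with different characteristic noise", {
  set.seed(32)
  res <- rbind(matrix(rnorm(150 * 80, sd = 1.0), 150, 80),
               matrix(rnorm(150 * 80, sd = 0.5), 150, 80))
  ear <- estimate_ear(res, seed = 1)$ear
  ratio <- median(ear[1:150, ]) / median(ear[151:300, ])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("EAR bottoms out at the floor on exact-fit data", {
  set.seed(33)
  X <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 30), 2, 30)
  fit <- als_decompose(X, 2, tol = 1e-10)
  res <- residual_matrix(X, fitted(fit))
  ear <- estimate_ear(res, seed = 1)$ear
  expect_lt(max(ear), 1e-4)
})

test_that("the cell standard-error formula matches its closed form", {
  expect_equal(standard_error(1, 38, 38, 2), 2 * sqrt(2) / 6,
               tolerance = 1e-12)
  expect_equal(standard_error(1, 38, 38, 2), 0.4714, tolerance = 1e-4)
  # divergence as counts approach the dimensionality
  expect_equal(standard_error(1, 2, 30, 2), Inf)
  expect_equal(standard_error(1, 30, 2, 2), Inf)
  expect_error(standard_error(1, 1, 30, 2), "invalid counts")
  # strictly decreasing in r and c, increasing in ear and d
  expect_gt(standard_error(1, 10, 20, 2), standard_error(1, 11, 20, 2))
  expect_gt(standard_error(1, 10, 20, 2), standard_error(1, 10, 21, 2))
  expect_gt(standard_error(2, 10, 20, 2), standard_error(1, 10, 20, 2))
  expect_gt(standard_error(1, 20, 20, 3), standard_error(1, 20, 20, 2))
  # the alternative denominator convention is available
  expect_equal(standard_error(1, 38, 38, 2, variant = "rc_minus_1"),
               2 * sqrt(2) / (37 * 37)^(1 / 4), tolerance = 1e-12)
})

test_that("the one-facet one-dimension reduction uses n - 1", {
  expect_equal(standard_error_1d(0.5, 26), 0.1)
  expect_equal(standard_error_1d(1, 1), Inf)
})

test_that("ESE reproduces a constant SE matrix and tracks SE closely", {
  se_const <- matrix(0.7, 40, 30)
  ese <- estimate_ese(se_const, seed = 1)$ese
  expect_true(all(abs(ese - 0.7) / 0.7 < 0.1))

  hf <- hetero_fit()
  ese_fit <- estimate_ese(hf$noise$se, seed = 2)
  expect_equal(dim(ese_fit$row_coords), c(300L, 2L))
  expect_equal(dim(ese_fit$col_coords), c(2L, 80L))
  expect_gt(cor(as.vector(ese_fit$ese), as.vector(hf$noise$se)), 0.9)
})

test_that("misfit standardizes residuals by their expected scale", {
  X <- matrix(1, 2, 2); E <- X
  mf <- misfit(X, E, matrix(0.5, 2, 2))
  expect_equal(mf$cell, matrix(0, 2, 2))
  expect_true(all(mf$interpretable))

  E2 <- matrix(0, 1, 1)
  mf2 <- misfit(matrix(1, 1, 1), E2, matrix(0.5, 1, 1))
  expect_equal(mf2$cell[1, 1], 2.0)

  # Gaussian residuals standardized by the true sd: mean square near 1
  set.seed(44)
  s <- outer(exp(rnorm(300, 0, 0.4)), exp(rnorm(100, 0, 0.4)))
  E3 <- matrix(0, 300, 100)
  X3 <- E3 + matrix(rnorm(300 * 100), 300, 100) * s
  mf3 <- misfit(X3, E3, s)
  expect_gt(mean(mf3$cell^2), 0.9)
  expect_lt(mean(mf3$cell^2), 1.1)
})

test_that("the standard error is calibrated against known truth", {
  hf <- hetero_fit()
  err <- abs(fitted(hf$fit) - hf$sim$truth$T)
  ratio <- err / hf$noise$se
  expect_gt(median(ratio), 0.4)
  expect_lt(median(ratio), 2.0)
  expect_gt(cor(as.vector(hf$noise$se), as.vector(err),
                method = "spearman"), 0.2)
})

test_that("SE is conservative at small noise and less so as noise grows", {
  ratios <- vapply(c(0.1, 4), function(nb) {
    spec <- simulation_spec(n_persons = 200, n_items = 60, true_d = 4,
                            noise_base = nb, missing_pattern = "random",
                            seed = 51)
    sim <- simulate_dataset(spec)
    fit <- als_decompose(sim$X, 4, tol = 1e-7, max_iter = 100)
    nm <- estimate_noise_model(sim$X, fit, seed = 1)
    median(abs(fitted(fit) - sim$truth$T) / nm$se)
  }, 0)
  expect_lt(ratios[1], 1)          # error overestimated when noise is small
  expect_gt(ratios[2], ratios[1])  # bias moves toward underestimation
})
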