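# The data containers and the ALS decomposition engine.

test_that("dot_estimate is the plain dot product and checks lengths", {
  expect_equal(dot_estimate(c(1, 2), c(3, 4)), 11)
  expect_equal(dot_estimate(c(0, 0), c(5, -7)), 0)
  expect_equal(dot_estimate(c(1, 0), c(5, 7)), 5)
  expect_error(dot_estimate(1:3, 1:2), "dimension")
})

test_that("solve_coordinates solves masked least squares exactly", {
  # identity basis passes the observations straight through (pad to stay
  # overdetermined)
  B <- rbind(diag(2), diag(2))
  expect_equal(solve_coordinates(c(3, 4, 3, 4), B), c(3, 4))

  # consistent overdetermined system: exact solution, zero residual
  set.seed(1)
  A <- matrix(rnorm(8), 4, 2)
  b_true <- c(2, -1)
  y <- drop(A %*% b_true)
  sol <- solve_coordinates(y, A)
  expect_equal(sol, b_true, tolerance = 1e-12)
  expect_lt(max(abs(y - A %*% sol)), 1e-12)

  # masked entries are ignored
  y2 <- y; y2[2] <- NA
  expect_equal(solve_coordinates(y2, A), b_true, tolerance = 1e-12)
})

test_that("solve_coordinates beats every point on a grid around it", {
  set.seed(7)
  A <- matrix(rnorm(20), 10, 2)
  y <- drop(A %*% c(1.5, -0.7)) + rnorm(10, sd = 0.3)
  sol <- solve_coordinates(y, A)
  rss <- function(b) sum((y - A %*% b)^2)
  grid <- expand.grid(d1 = seq(-0.05, 0.05, by = 0.01),
                      d2 = seq(-0.05, 0.05, by = 0.01))
  grid_rss <- apply(grid, 1, function(d) rss(sol + d))
  expect_true(all(rss(sol) <= grid_rss + 1e-12))
})

test_that("solve_coordinates reports underdetermined and singular systems", {
  expect_error(solve_coordinates(c(1, 2), matrix(1, 2, 2)), "underdetermined")
  A <- cbind(1:5, 2 * (1:5))          # rank 1
  expect_warning(sol <- solve_coordinates(c(1, 2, 3, 4, 5), A),
                 "rank-deficient")
  expect_length(sol, 2)
})

test_that("orthonormalize returns an orthonormal basis of the same span", {
  set.seed(3)
  R <- matrix(rnorm(40), 10, 4)
  Q <- orthonormalize(R)
  expect_equal(crossprod(Q), diag(4), tolerance = 1e-10)
  # span preservation: projection matrix unchanged
  P1 <- R %*% solve(crossprod(R)) %*% t(R)
  P2 <- Q %*% t(Q)
  expect_equal(P1, P2, tolerance = 1e-8)
  # idempotent on an already-orthonormal input (sign convention fixed)
  expect_equal(orthonormalize(Q), Q, tolerance = 1e-12)
  expect_error(orthonormalize(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("data_matrix enforces its invariants", {
  m <- matrix(1:6, 2, 3)
  expect_error(data_matrix(m, row_ids = c("a", "a")), "unique")
  m2 <- m; m2[1, ] <- NA
  expect_error(data_matrix(m2), "observed")
  dm <- data_matrix(m)
  expect_s3_class(dm, "data_matrix")
  expect_equal(dim(dm), c(2L, 3L))
})

test_that("ALS reproduces a complete rank-1 product exactly", {
  set.seed(5)
  X <- outer(rnorm(30), rnorm(12))
  fit <- als_decompose(X, 1, tol = 1e-10)
  expect_lt(max(abs(fitted(fit) - X)), 1e-6)
  expect_true(fit$converged)
})

test_that("ALS recovers held-out true values on noise-free low-rank data", {
  set.seed(9)
  R_true <- matrix(rnorm(200 * 6), 200, 6)
  C_true <- matrix(rnorm(6 * 100), 6, 100)
  T_mat <- R_true %*% C_true
  X <- T_mat
  X[sample(length(X), round(0.25 * length(X)))] <- NA
  # guard solvability of the random deletion
  stopifnot(all(rowSums(!is.na(X)) > 7), all(colSums(!is.na(X)) > 7))
  fit <- als_decompose(X, 6, tol = 1e-9, max_iter = 200)
  expect_lt(max(abs(fitted(fit) - T_mat)), 1e-5)

  # the product is invariant to the seed even though R and C are not
  fit2 <- als_decompose(X, 6, seed = 99, init = "random",
                        tol = 1e-9, max_iter = 200)
  expect_lt(max(abs(fitted(fit2) - fitted(fit))), 1e-5)
  expect_gt(max(abs(fit2$R - fit$R)), 0.01)
})

test_that("ALS residual is non-increasing and R ends orthonormal", {
  spec <- simulation_spec(n_persons = 120, n_items = 50, true_d = 4,
                          noise_base = 1, missing_pattern = "random",
                          seed = 13)
  sim <- simulate_dataset(spec)
  fit <- als_decompose(sim$X, 4, tol = 1e-9, max_iter = 60)
  expect_true(all(diff(fit$rms_resid) <= 1e-10))
  expect_equal(crossprod(fit$R), diag(4), tolerance = 1e-8)
})

test_that("rows with too few observations are excluded with a warning", {
  set.seed(2)
  X <- outer(rnorm(20), rnorm(10)) + outer(rnorm(20), rnorm(10))
  X[3, 3:10] <- NA                     # row 3 keeps 2 obs <= d
  expect_warning(fit <- als_decompose(X, 2, tol = 1e-8), "excluding")
  expect_equal(fit$dropped_rows, "p3")
  expect_equal(nrow(fit$R), 19)
})

test_that("unknown anchor ids error", {
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("i", 1:5)))
  expect_error(als_decompose(X, 2, anchored_cols = "nope",
                             C_init = matrix(0, 2, 5)),
               "unknown anchor")
})

test_that("matrix CSV round-trips with missing cells", {
  dm <- data_matrix(matrix(c(1, NA, 3, 4.5, 5, NA), 2, 3,
                           dimnames = list(c("a", "b"), c("x", "y", "z"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_data_matrix(dm, path)
  back <- read_data_matrix(path)
  expect_equal(back$values, dm$values)
  expect_equal(back$row_ids, dm$row_ids)
})
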