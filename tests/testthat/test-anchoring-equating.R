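# Age-anchored calibration, common-item equating, item drift, and the bank.

test_that("age residualization leaves columns orthogonal to the age vector", {
  sim <- nf_instrument()
  ar <- age_residualize(sim$X$values, sim$ages)
  obs <- !is.na(sim$X$values)
  dots <- colSums(ar$age_vector * ifelse(obs, ar$residuals, 0))
  expect_lt(max(abs(dots)), 1e-8)
  expect_equal(sum(ar$age_vector^2), 1, tolerance = 1e-12)
  expect_error(age_residualize(sim$X$values, sim$ages[-1]), "one age per")
  bad_ages <- sim$ages; bad_ages[3] <- NA
  expect_error(age_residualize(sim$X$values, bad_ages), "p3")
})

test_that("age-anchored calibration recovers noise-free truth everywhere", {
  sim <- nf_instrument()
  cal <- age_anchored_calibration(sim$X$values, sim$ages, d_residual = 5,
                                  seed = 2, tol = 1e-10, max_iter = 150,
                                  refine_iter = 60)
  expect_lt(max(abs(fitted(cal) - sim$truth$T)), 1e-4)
  expect_equal(cal$dimensionality, 6L)
  expect_equal(cal$anchored_dims, 1L)
})

test_that("persons alike except in age differ only through the age loading", {
  sim <- nf_instrument()
  cal <- age_anchored_calibration(sim$X$values, sim$ages, d_residual = 5,
                                  seed = 2, tol = 1e-10, max_iter = 150,
                                  refine_iter = 60)
  # construct two synthetic persons sharing residual coordinates but with
  # different ages: their estimate difference is rank one in C[1,]
  R1 <- cal$R[1, ]; R2 <- R1; R2[1] <- R2[1] + 0.1
  d_est <- drop((R2 - R1) %*% cal$C)
  expect_equal(d_est, 0.1 * cal$C[1, ], tolerance = 1e-10)
})

test_that("anchored equating reproduces the joint calibration", {
  sim <- nf_instrument()
  X <- sim$X$values
  idsA <- colnames(X)[1:56]
  idsB <- colnames(X)[33:80]            # 24 common items
  joint <- nf_calibration()
  calA <- calibrate(X[, idsA], ages = sim$ages, ratings = sim$ratings,
                    d_residual = 5, seed = 2, tol = 1e-10, max_iter = 150,
                    refine_iter = 60)
  eq <- equate_forms(calA$bank, X[, idsB])
  expect_lt(max(abs(fitted(eq$coords) - fitted(joint$coords)[, idsB])), 1e-5)
  expect_lt(mean(eq$fit$rms_residual), 1e-6)
  expect_setequal(eq$coords$anchored_cols, intersect(idsA, idsB))
})

test_that("equating requires enough common items", {
  calA <- nf_calibration()
  X <- nf_instrument()$X$values
  disjoint <- X[, 1:10]
  colnames(disjoint) <- paste0("zz", 1:10)
  expect_error(equate_forms(calA$bank, disjoint), "common ids|under-identified")
  few <- X[, 1:6]                      # 6 common = D, under-identified
  expect_error(equate_forms(calA$bank, few), "under-identified")
})

test_that("item drift is 1 for identical coordinates and ~0 for noise", {
  C1 <- matrix(rnorm(6 * 30), 6, 30, dimnames = list(NULL, paste0("i", 1:30)))
  dr <- item_drift(C1, C1)
  expect_equal(dr$pooled, 1)
  expect_true(all(abs(dr$per_item - 1) < 1e-12))
  set.seed(3)
  C2 <- matrix(rnorm(6 * 30), 6, 30, dimnames = dimnames(C1))
  expect_lt(abs(item_drift(C1, C2)$pooled), 0.2)
  expect_error(item_drift(C1[, 1:3, drop = FALSE],
                          C2[, 4:6, drop = FALSE]), "no shared items")
})

test_that("disjoint person samples calibrate to the same item coordinates", {
  sim <- nf_instrument()
  X <- sim$X$values
  g1 <- seq(1, nrow(X), by = 2); g2 <- seq(2, nrow(X), by = 2)
  # common frame: anchor both groups on the full-data item bank C, then
  # refit item coordinates per group from the anchored person solves
  cal <- nf_calibration()
  coords_for <- function(rows) {
    R <- t(vapply(rows, function(n)
      solve_coordinates(X[n, ], t(cal$coords$C)), numeric(6)))
    vapply(seq_len(ncol(X)), function(i)
      solve_coordinates(X[rows, i], R), numeric(6))
  }
  C1 <- coords_for(g1); C2 <- coords_for(g2)
  colnames(C1) <- colnames(C2) <- colnames(X)
  expect_gt(item_drift(C1, C2)$pooled, 0.99)
})

test_that("an item bank round-trips through JSON and scores consistently", {
  cal <- nf_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_item_bank(cal$bank, path)
  back <- read_item_bank(path)
  expect_equal(back$C, cal$bank$C, tolerance = 1e-12)
  expect_equal(back$dimensionality, cal$bank$dimensionality)
  expect_equal(back$metrics, cal$bank$metrics)
  expect_equal(back$transform, cal$bank$transform, tolerance = 1e-12)
  expect_equal(back$cut_scores, cal$bank$cut_scores)
  # bank D equals calibration D
  expect_equal(cal$bank$dimensionality, cal$coords$dimensionality)
  # a calibration person rescored from the deserialized bank matches
  X <- nf_instrument()$X$values
  resp <- X[5, !is.na(X[5, ])]
  sc <- score_person(resp, back)
  expect_equal(sc$drs, unname(cal$drs[5]), tolerance = 1e-6)
})

test_that("bank assembly validates dimensional consistency", {
  cal <- nf_calibration()
  expect_error(build_item_bank(cal$coords, cal$noise, cal$metrics,
                               construct_coords = list(x = rnorm(3)),
                               transform = cal$bank$transform),
               "assembly error")
  expect_error(build_item_bank(cal$coords, cal$noise, cal$metrics,
                               construct_coords = cal$bank$construct,
                               transform = cal$bank$transform,
                               cut_scores = c(50, 45, 55)),
               "strictly increasing")
})
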